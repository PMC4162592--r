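# Tabulated loop entropies: construction, serialization, extrapolation.

#' Build the loop-entropy table by lattice enumeration
#'
#' Enumerates hairpin, internal/bulge and pseudoknot-spanning loops up to
#' the cap, plus mismatch-constrained hairpin and internal loops, and
#' tabulates dS_loop = ln(omega_closed/omega_open) in units of R. The
#' enumeration is deterministic, so regenerating with the same caps is
#' bit-identical.
#'
#' @param max_total enumeration cap on total unpaired length.
#' @param pk_max_loop,pk_max_helix caps for the pseudoknot-spanning table.
#' @param mismatches also tabulate mismatch-constrained loops.
#' @param engine enumeration engine (see [enumerate_loop()]).
#' @param verbose print progress.
#' @return a `loop_entropy_table` object.
#' @export
build_entropy_tables <- function(max_total = 8, pk_max_loop = 6,
                                 pk_max_helix = 6, mismatches = TRUE,
                                 engine = "production", verbose = FALSE) {
  rows <- list()
  add <- function(type, s1, s2, p1, p2, cnt) {
    rows[[length(rows) + 1]] <<- tibble(
      loop_type = type, size1 = s1, size2 = s2, pos1 = p1, pos2 = p2,
      omega_closed = cnt$omega_closed, omega_open = cnt$omega_open,
      entropy = if (cnt$omega_closed == 0) -Inf else
        log(cnt$omega_closed / cnt$omega_open),
      provenance = "enumerated")
  }
  for (L in 3:max_total) {
    if (verbose) message("hairpin L=", L)
    add("hairpin", L, 0L, 0L, 0L, enumerate_loop("hairpin", L, max_total,
                                                 engine = engine))
  }
  for (L1 in 0:max_total) for (L2 in 0:(max_total - L1)) {
    if (L1 + L2 < 1) next
    if (verbose) message("internal ", L1, ",", L2)
    add("internal", L1, L2, 0L, 0L,
        enumerate_loop("internal", c(L1, L2), max_total, engine = engine))
  }
  for (h in 2:pk_max_helix) for (L in 1:pk_max_loop) {
    if (verbose) message("pk L=", L, " h=", h)
    add("pk", L, h, 0L, 0L,
        enumerate_loop("pk", c(L, h), pk_max_loop, engine = engine))
  }
  if (mismatches) {
    for (L in 5:max_total) for (u in 1:(L - 4)) for (v in (u + 4):L) {
      if (verbose) message("hairpin_mm L=", L, " (", u, ",", v, ")")
      add("hairpin_mm", L, 0L, u, v,
          enumerate_loop("hairpin", L, max_total, cbind(u, v), engine = engine))
    }
    for (L1 in 1:(max_total - 1)) for (L2 in 1:(max_total - L1))
      for (u in 1:L1) for (v in 1:L2) {
        if (verbose) message("internal_mm ", L1, ",", L2, " (", u, ",", v, ")")
        add("internal_mm", L1, L2, u, v,
            enumerate_loop("internal", c(L1, L2), max_total, cbind(u, v),
                           engine = engine))
      }
  }
  tab <- dplyr::bind_rows(rows)
  .vf_entropy_table(tab, meta = list(lattice = "diamond",
                                     bonds_per_nt = 2L,
                                     max_total = max_total,
                                     pk_max_loop = pk_max_loop,
                                     pk_max_helix = pk_max_helix,
                                     engine = engine))
}

.vf_entropy_table <- function(entries, meta) {
  obj <- list(entries = entries, meta = meta)
  obj$fits <- .vf_entropy_fits(entries)
  class(obj) <- "loop_entropy_table"
  obj
}

# Jacobson-Stockmayer-form fits dS(L) = a - c*ln(L) for extrapolation
.vf_entropy_fits <- function(entries) {
  hp <- entries[entries$loop_type == "hairpin" & is.finite(entries$entropy), ]
  fh <- NULL
  if (nrow(hp) >= 4) {
    # fit on the non-increasing tail from the entropy-maximal size
    L0 <- hp$size1[which.max(hp$entropy)]
    hpf <- hp[hp$size1 >= L0, ]
    if (nrow(hpf) < 4) hpf <- hp
    fh <- coef(lm(entropy ~ log(size1), data = hpf))
  }
  int <- entries[entries$loop_type == "internal" & is.finite(entries$entropy), ]
  tot <- int$size1 + int$size2
  fi <- if (length(unique(tot)) >= 4) coef(lm(int$entropy ~ log(tot))) else NULL
  pk <- entries[entries$loop_type == "pk" & is.finite(entries$entropy), ]
  pkfits <- lapply(sort(unique(pk$size2)), function(h) {
    d <- pk[pk$size2 == h, ]
    if (nrow(d) < 4) return(NULL)
    coef(lm(entropy ~ log(size1), data = d))
  })
  names(pkfits) <- as.character(sort(unique(pk$size2)))
  as_ac <- function(f) if (is.null(f)) NULL else c(a = unname(f[1]), c = unname(-f[2]))
  list(hairpin = as_ac(fh), internal = as_ac(fi),
       pk = lapply(pkfits, as_ac))
}

#' Serialize / read a loop-entropy table
#'
#' Tab-separated text with one row per entry (loop type, sizes, mismatch
#' positions, conformation counts, dS/R, provenance).
#'
#' @param table a `loop_entropy_table`.
#' @param path file path.
#' @return `write_entropy_table`: the path, invisibly;
#'   `read_entropy_table`: the table object.
#' @export
write_entropy_table <- function(table, path) {
  df <- as.data.frame(table$entries)
  df$entropy <- sprintf("%.12g", df$entropy)
  hdr <- sprintf("# loop entropy table | lattice=%s bonds_per_nt=%d max_total=%d pk_max_loop=%d pk_max_helix=%d",
                 table$meta$lattice, table$meta$bonds_per_nt,
                 table$meta$max_total, table$meta$pk_max_loop,
                 table$meta$pk_max_helix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_entropy_table
#' @export
read_entropy_table <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[a-z0-9]+", hdr))[[1]]
  meta <- list(lattice = "diamond", bonds_per_nt = 2L)
  for (x in kv) {
    p <- strsplit(x, "=")[[1]]
    meta[[p[1]]] <- if (grepl("^[0-9]+$", p[2])) as.integer(p[2]) else p[2]
  }
  df <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  df$entropy <- as.numeric(df$entropy)
  df$omega_closed <- as.numeric(df$omega_closed)
  df$omega_open <- as.numeric(df$omega_open)
  .vf_entropy_table(as_tibble(df), meta = meta)
}

#' Default loop-entropy table
#'
#' The pre-enumerated table shipped with the package (diamond lattice, two
#' bonds per nucleotide, loops up to 8 unpaired nt, pseudoknot-spanning
#' loops up to length 6 over helices of 2-6 bp, mismatch-constrained
#' variants). Cached per session.
#'
#' @return a `loop_entropy_table` object.
#' @export
loop_entropy_table <- function() {
  hit <- .vf_cache[["default_entropy_table"]]
  if (!is.null(hit)) return(hit)
  path <- system.file("extdata", "loop_entropies.tsv", package = "vfold",
                      mustWork = TRUE)
  tab <- read_entropy_table(path)
  .vf_cache[["default_entropy_table"]] <- tab
  tab
}

#' @export
print.loop_entropy_table <- function(x, ...) {
  cat("<loop_entropy_table>", nrow(x$entries), "entries;",
      "lattice:", x$meta$lattice, "\n")
  print(dplyr::count(x$entries, .data$loop_type))
  invisible(x)
}

# internal-loop entropy for any sizes (table or ln-extrapolation); (0,0) = 0
.vf_s_int_any <- function(entropies, a, b) {
  if (a + b == 0) return(0)
  e <- entropies$entries
  hit <- e[e$loop_type == "internal" & e$size1 == a & e$size2 == b, ]
  if (nrow(hit) == 1) return(hit$entropy)
  f <- entropies$fits$internal
  unname(f["a"] - f["c"] * log(a + b))
}

#' Loop entropy with extrapolation beyond the enumerated range
#'
#' Returns the enumerated entry when present; otherwise evaluates the
#' Jacobson-Stockmayer-form fit dS(L) = a - c ln L for that loop type
#' (internal loops on the total length; pseudoknot loops per spanned helix
#' length) and marks the value as extrapolated.
#'
#' @param table a `loop_entropy_table`.
#' @param loop_type `"hairpin"`, `"internal"`, or `"pk"`.
#' @param sizes loop sizes (see [enumerate_loop()]).
#' @return list with `entropy` (units of R) and `provenance`.
#' @export
extrapolate_entropy <- function(table, loop_type, sizes) {
  sizes <- as.integer(sizes)
  e <- table$entries
  if (loop_type == "hairpin") {
    hit <- e[e$loop_type == "hairpin" & e$size1 == sizes[1], ]
    if (nrow(hit) == 1)
      return(list(entropy = hit$entropy, provenance = "enumerated"))
    f <- table$fits$hairpin
    if (is.null(f))
      abort("too few enumerated hairpin sizes to extrapolate",
            class = "vfold_fit_error")
    if (sizes[1] < 3)
      abort("hairpin loops need >= 3 unpaired nt", class = "vfold_invalid_loop")
    return(list(entropy = unname(f["a"] - f["c"] * log(sizes[1])),
                provenance = "extrapolated"))
  }
  if (loop_type %in% c("internal", "bulge")) {
    if (loop_type == "bulge") sizes <- c(sizes[1], 0L)
    hit <- e[e$loop_type == "internal" & e$size1 == sizes[1] &
               e$size2 == sizes[2], ]
    if (nrow(hit) == 1)
      return(list(entropy = hit$entropy, provenance = "enumerated"))
    f <- table$fits$internal
    if (is.null(f))
      abort("too few enumerated internal sizes to extrapolate",
            class = "vfold_fit_error")
    return(list(entropy = unname(f["a"] - f["c"] * log(sum(sizes))),
                provenance = "extrapolated"))
  }
  if (loop_type %in% c("pk", "pk_loop")) {
    L <- sizes[1]; h <- sizes[2]
    hmax <- max(e$size2[e$loop_type == "pk"])
    if (h > hmax) {
      .vf_once("pk_h_clamp", function()
        warn(sprintf("pseudoknot-spanned helix longer than the tabulated maximum (%d bp); clamping", hmax)))
      h <- hmax
    }
    hit <- e[e$loop_type == "pk" & e$size1 == L & e$size2 == h, ]
    if (nrow(hit) == 1)
      return(list(entropy = hit$entropy, provenance = "enumerated"))
    f <- table$fits$pk[[as.character(h)]]
    if (is.null(f))
      abort("too few enumerated pseudoknot sizes to extrapolate",
            class = "vfold_fit_error")
    return(list(entropy = unname(f["a"] - f["c"] * log(L)),
                provenance = "extrapolated"))
  }
  abort(sprintf("unknown loop type '%s'", loop_type),
        class = "vfold_invalid_loop")
}
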