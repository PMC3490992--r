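# Independent oracles used to cross-check the implementation.

# Brute-force flood-fill patch labeling: scans cells, grows each component by
# an explicit frontier queue. Independent of the graph-based implementation.
oracle_patch_count <- function(bin, connectivity = 4L, min_patch_size = 3L) {
  nr <- nrow(bin); nc <- ncol(bin)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  offs <- if (connectivity == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0] || is.na(bin[r0, c0])) next
    b <- bin[r0, c0]
    frontier <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    size <- 0L
    while (length(frontier)) {
      cell <- frontier[[length(frontier)]]
      frontier[[length(frontier)]] <- NULL
      size <- size + 1L
      for (o in offs) {
        r <- cell[1] + o[1]; c <- cell[2] + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && !seen[r, c] &&
            !is.na(bin[r, c]) && bin[r, c] == b) {
          seen[r, c] <- TRUE
          frontier[[length(frontier) + 1]] <- c(r, c)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sum(sizes >= min_patch_size)
}

# Aspect by an explicit per-cell finite-difference loop (no vectorized paths
# shared with the implementation).
oracle_aspect <- function(hm) {
  z <- hm$values
  z[!hm$mask] <- NA
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    block <- c(z[r, c], z[r + 1, c], z[r - 1, c], z[r, c + 1], z[r, c - 1])
    if (anyNA(block)) next
    gn <- (z[r + 1, c] - z[r - 1, c]) / (2 * hm$spacing_row)
    ge <- (z[r, c + 1] - z[r, c - 1]) / (2 * hm$spacing_col)
    if (sqrt(gn^2 + ge^2) < 1e-12) next
    out[r, c] <- (atan2(-ge, -gn) * 180 / pi) %% 360
  }
  out
}

# A random binned field with NA holes, for oracle-equivalence loops.
random_binned_field <- function(nr, nc, n_bins = 8L, na_frac = 0.1) {
  b <- matrix(sample(0:(n_bins - 1L), nr * nc, replace = TRUE), nr, nc)
  b[stats::runif(nr * nc) < na_frac] <- NA
  structure(list(bin = b, n_bins = n_bins, offset_deg = 0),
            class = "binned_field")
}

# A bumpy random surface whose aspects exercise all bins.
random_cusp_map <- function(seed = 1L, n = 61L) {
  make_surface(surface_spec("cusp_field", n_rows = n, n_cols = n,
                            n_cusps = 4L, cusp_width = 0.15,
                            seed = seed))
}

table1 <- function() derive_measures(load_specimen_table("table1"))
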