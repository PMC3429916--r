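# Independent oracles used across tests.  These deliberately avoid the
# package's own canonicalization path: equivalence classes are found by
# orbit traversal under the generators (rotate-by-one, reverse-complement),
# not by lexicographic minimisation.

oracle_rotate1 <- function(s) {
  paste0(substr(s, 2, nchar(s)), substr(s, 1, 1))
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# primitive iff no proper rotation by a divisor period reproduces the string
oracle_is_primitive <- function(s) {
  k <- nchar(s)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0) {
      r <- s
      for (i in seq_len(d)) r <- oracle_rotate1(r)
      if (r == s) return(FALSE)
    }
  }
  TRUE
}

# Partition all length-k strings into orbits by BFS under the generators;
# returns the list of orbits restricted to primitive strings.
oracle_orbits <- function(k) {
  alph <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(alph), k),
                                 list(stringsAsFactors = FALSE)))
  all_strings <- do.call(paste0, grid)
  prim <- all_strings[vapply(all_strings, oracle_is_primitive, logical(1))]
  seen <- new.env(parent = emptyenv())
  orbits <- list()
  for (s in prim) {
    if (!is.null(seen[[s]])) next
    orbit <- character(0)
    queue <- s
    while (length(queue) > 0) {
      x <- queue[[1]]; queue <- queue[-1]
      if (!is.null(seen[[x]])) next
      seen[[x]] <- TRUE
      orbit <- c(orbit, x)
      queue <- c(queue, oracle_rotate1(x), oracle_revcomp(x))
    }
    orbits[[length(orbits) + 1]] <- sort(orbit)
  }
  orbits
}

# random DNA motif of length 1..6
random_motif <- function(max_len = 6) {
  k <- sample(max_len, 1)
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

# random mutation-call set over a handful of markers
random_calls <- function(n_calls, markers = paste0("M", 1:5),
                         lines = paste0("L", 1:20)) {
  d <- sample(c(-9:-1, 1:9), n_calls, replace = TRUE)
  tibble::tibble(
    marker_id = sample(markers, n_calls, replace = TRUE),
    line_id = sample(lines, n_calls, replace = TRUE),
    delta_units = as.integer(d)
  )
}

# interval overlap fraction relative to the truth interval
overlap_frac <- function(start, end, tstart, tend) {
  ov <- pmin(end, tend) - pmax(start, tstart) + 1
  pmax(ov, 0) / (tend - tstart + 1)
}
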