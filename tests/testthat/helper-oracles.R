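# Independent plain-R oracles used to validate the compiled clustering
# routines. These deliberately avoid the package's own C++ code paths.

# within-cluster sum of squares, plain R
r_sse <- function(X, labels) {
  sum(vapply(unique(labels), function(g) {
    sub <- X[labels == g, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, 0))
}

# all circularly contiguous k-arc partitions of 12 months, as label vectors
# (arcs numbered in cut order), enumerated from cut-set combinations
r_contiguous_partitions <- function(k, n = 12) {
  combs <- combn(n, k)
  lapply(seq_len(ncol(combs)), function(j) {
    cuts <- combs[, j]
    lab <- rep(k, n)                 # months before the first cut wrap
    for (a in seq_len(k)) {
      from <- cuts[a]
      to <- if (a < k) cuts[a + 1] - 1 else n
      lab[from:to] <- a
    }
    lab
  })
}

# exhaustive best contiguous partition by SSE (first = lexicographic ties)
r_best_contiguous <- function(X, k) {
  parts <- r_contiguous_partitions(k, nrow(X))
  sses <- vapply(parts, function(p) r_sse(X, p), 0)
  best <- which(sses < min(sses) + 1e-9)[1]
  list(labels = parts[[best]], sse = sses[best])
}

# exhaustive best bipartition (all 2^11 - 1 nonempty splits) by SSE
r_best_bipartition_sse <- function(X) {
  best <- Inf
  for (m in 1:2046) {
    lab <- as.integer(intToBits(m)[1:12]) + 1L
    if (length(unique(lab)) < 2) next
    s <- r_sse(X, lab)
    if (s < best) best <- s
  }
  best
}

# do two labelings describe the same partition (up to label names)?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# minimal hand-built pixel for zonation tests
flat_pixel <- function(tmid = rep(15, 12), tspan = 5, precip = rep(60, 12),
                       pet = rep(60, 12), srad = rep(15, 12),
                       ndvi = rep(0.4, 12)) {
  pixel_climate(tmin = tmid - tspan, tmax = tmid + tspan, precip = precip,
                srad = srad, ndvi = ndvi, pet = pet)
}

# reference record in the data.frame layout the scorers accept
make_record <- function(labels, city = "c", country = "x",
                        lon = 0, lat = 0) {
  rec <- data.frame(city = city, country = country, lon = lon, lat = lat,
                    stringsAsFactors = FALSE)
  rec[tolower(month.abb)] <- as.list(labels)
  rec
}
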