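# Shared fixtures, built in code and cached across test files.

assay_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = assay_cache)) {
    assign(name, force(expr), envir = assay_cache)
  }
  get(name, envir = assay_cache)
}

# full-density assay: 4.1 kb homology, 82 markers, central cut site
full_assay <- function() cached("full", synthetic_assay())

# scaled-down assay for read-level work
toy_assay <- function() {
  cached("toy", synthetic_assay(homology_len = 600, n_markers = 10, site_start = 280))
}

# allele pair + marker map with markers at chosen recipient positions,
# anchored at a bare numeric position (no nuclease site)
make_map <- function(positions = seq(50, 400, by = 50), len = 450,
                     anchor = 225, seed = 99) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rec <- sample(bases, len, replace = TRUE)
  don <- rec
  for (p in positions) don[p + 1] <- sample(setdiff(bases, rec[p + 1]), 1)
  pair <- allele_pair(paste(rec, collapse = ""), paste(don, collapse = ""))
  map <- derive_marker_map(pair, anchor)
  list(pair = pair, map = map, anchor = anchor)
}

# independent linear-scan segmentation oracle (no rle, no dplyr)
oracle_segments <- function(genotype, positions) {
  info <- which(genotype != "N")
  eff <- genotype
  for (i in which(genotype == "N")) {
    left <- info[info < i]
    right <- info[info > i]
    eff[i] <- if (length(left) && length(right) &&
      genotype[max(left)] == genotype[min(right)]) {
      genotype[max(left)]
    } else {
      NA_character_
    }
  }
  segs <- list()
  cur_state <- NA
  for (i in seq_along(eff)) {
    if (is.na(eff[i])) next
    if (!identical(eff[i], cur_state)) {
      segs[[length(segs) + 1]] <- list(state = eff[i], first = i, last = i)
      cur_state <- eff[i]
    } else {
      segs[[length(segs)]]$last <- i
    }
  }
  do.call(rbind, lapply(segs, function(s) {
    data.frame(state = s$state, first_marker = s$first, last_marker = s$last)
  }))
}

# full-enumeration two-sided Fisher oracle for a 2x2 table
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random genotype vector with at least one informative marker
random_genotype <- function(n, p_n = 0.05) {
  g <- sample(c("R", "D", "H"), n, replace = TRUE)
  g[runif(n) < p_n] <- "N"
  if (all(g == "N")) g[sample(n, 1)] <- "R"
  g
}
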