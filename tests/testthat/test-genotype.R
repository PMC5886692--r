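test_that("demultiplexing assigns exact and near-exact barcodes and rejects distant ones", {
  assay <- toy_assay()
  set.seed(21)
  bcs <- random_barcodes(4)
  prim <- universal_primers()
  core <- assay$truth$recipient_seq
  mk_read <- function(bc, product) {
    pp <- prim[prim$product_id == product, ]
    paste0(
      bc, pp$fwd, core,
      as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(paste0(pp$rev, bc))))
    )
  }
  flipn <- function(bc, n) {
    ch <- strsplit(bc, "")[[1]]
    for (i in seq_len(n)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  reads <- tibble::tibble(
    read_id = c("exact", "two_mm", "three_mm"),
    sequence = c(
      mk_read(bcs$barcode[2], "P_FULL"),
      mk_read(flipn(bcs$barcode[3], 2), "P_TRUNC"),
      mk_read(flipn(bcs$barcode[4], 3), "P_FULL")
    )
  )
  dmx <- demultiplex(reads, bcs)
  expect_equal(dmx$status, c("assigned", "assigned", "unassigned"))
  expect_equal(dmx$recombinant_id[1:2], bcs$recombinant_id[2:3])
  expect_equal(dmx$product_id[1:2], c("P_FULL", "P_TRUNC"))
  expect_equal(dmx$core[1], core)
  expect_match(dmx$reason[3], "barcode")
  # duplicate barcodes are rejected
  expect_error(
    demultiplex(reads, tibble::tibble(
      recombinant_id = c("a", "b"), barcode = rep(bcs$barcode[1], 2)
    )),
    "duplicate"
  )
})

test_that("simulated reads demultiplex back to their recombinant and product", {
  assay <- toy_assay()
  set.seed(22)
  ev <- simulate_dsbr(clean_params(resection_mean = 150), assay$map, assay$break_site, 5)
  obs <- observe_colony(ev)
  bcs <- random_barcodes(5)
  reads <- emit_reads(obs, assay$pair, assay$map, bcs, depth = 10, error_rate = 0.005)
  dmx <- demultiplex(reads, bcs)
  truth <- do.call(rbind, strsplit(dmx$read_id, "|", fixed = TRUE))
  correct <- dmx$status == "assigned" &
    dmx$recombinant_id == truth[, 1] & dmx$product_id == truth[, 2]
  expect_gte(mean(correct), 0.99)
})

test_that("read profiles call parental, chimeric and error bases per definition", {
  assay <- toy_assay()
  map <- assay$map
  m <- tibble::as_tibble(map)
  n_mark <- nrow(m)
  # a read equal to the donor reference is all-D
  expect_equal(
    call_read_profile(assay$pair$donor_seq, assay$pair, map),
    rep("D", n_mark)
  )
  # chimera spliced at the break: recipient for upstream markers, donor beyond
  b <- assay$break_site$cut_center
  chim <- paste0(
    substr(assay$pair$recipient_seq, 1, floor(b)),
    substr(assay$pair$donor_seq, map_donor_coordinate(assay$pair, floor(b)) + 1, nchar(assay$pair$donor_seq))
  )
  expect_equal(
    call_read_profile(chim, assay$pair, map),
    ifelse(m$pos_recipient < b, "R", "D")
  )
  # a non-parental base at a marker column is N, others unaffected
  third_base <- function(r, d) setdiff(c("A", "C", "G", "T"), c(r, d))[1]
  mut <- strsplit(assay$pair$recipient_seq, "")[[1]]
  mut[m$pos_recipient[3] + 1] <- third_base(m$recipient_base[3], m$donor_base[3])
  prof <- call_read_profile(paste(mut, collapse = ""), assay$pair, map)
  expect_equal(prof[3], "N")
  expect_equal(prof[-3], rep("R", n_mark - 1))
  # garbage read: all-N with a low-identity flag
  set.seed(23)
  junk <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  pr <- call_read_profiles(junk, assay$pair, map)
  expect_equal(pr[[1]], rep("N", n_mark))
  expect_true(attr(pr, "low_identity")[1])
})

test_that("species clustering groups by profile with N-compatibility merging", {
  p_x <- c("R", "R", "D", "D")
  p_y <- c("D", "D", "R", "R")
  sp <- cluster_species(rep(list(p_x), 10))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$support, 10)
  expect_equal(sp$fraction, 1.0)

  sp2 <- cluster_species(c(rep(list(p_x), 6), rep(list(p_y), 6)))
  expect_equal(nrow(sp2), 2)
  expect_equal(sp2$support, c(6, 6))

  p_xn <- c("R", "N", "D", "D")
  sp3 <- cluster_species(c(rep(list(p_x), 9), list(p_xn)))
  expect_equal(nrow(sp3), 1)
  expect_equal(sp3$support, 10)
  expect_equal(sp3$profile[[1]], p_x)

  # an N-profile merges into the *largest* compatible cluster
  sp4 <- cluster_species(c(rep(list(p_x), 3), rep(list(p_y), 5), list(c("N", "N", "R", "R"))))
  expect_equal(sp4$support, c(6, 3))
  expect_equal(sp4$profile[[1]], p_y)

  expect_error(cluster_species(list()), "no profiles")
})

test_that("QC passes at most two major species per product", {
  mk_species <- function(support) {
    n <- sum(support)
    structure(
      tibble::tibble(
        species = seq_along(support),
        profile = replicate(length(support), c("R", "R"), simplify = FALSE),
        support = support, fraction = support / n
      ),
      class = c("species_table", class(tibble::tibble()))
    )
  }
  one <- mk_species(10)
  two <- mk_species(c(6, 5))
  expect_true(qc_event(one, two)$qc_pass)
  # three comparable species are spurious
  three <- mk_species(c(8, 7, 5)) # fractions 0.4 / 0.35 / 0.25
  v <- qc_event(three, one)
  expect_false(v$qc_pass)
  expect_equal(v$n_major_trunc, 3)
  # a singleton error species below both thresholds does not count
  noisy <- mk_species(c(10, 9, 1)) # third: support 1, fraction 0.05
  expect_true(qc_event(noisy, one)$qc_pass)
  expect_equal(qc_event(noisy, one)$n_major_trunc, 2)
})

test_that("product genotype diagnoses hetDNA exactly where major species disagree R vs D", {
  mk <- function(p1, p2) {
    structure(
      tibble::tibble(
        species = 1:2, profile = list(p1, p2),
        support = c(6, 5), fraction = c(6, 5) / 11
      ),
      class = c("species_table", class(tibble::tibble()))
    )
  }
  sp <- mk(
    c("D", "D", "D", "D", "R", "R", "R", "R"),
    c("D", "D", "D", "D", "D", "D", "R", "R")
  )
  expect_equal(
    product_genotype(sp)$genotype,
    c("D", "D", "D", "D", "H", "H", "R", "R")
  )
  # single major species: its profile, never H
  single <- structure(
    tibble::tibble(
      species = 1, profile = list(rep("R", 4)),
      support = 10, fraction = 1
    ),
    class = c("species_table", class(tibble::tibble()))
  )
  expect_equal(product_genotype(single)$genotype, rep("R", 4))
  # exhaustive per-marker combination rule over all call pairs
  calls <- c("R", "D", "N")
  for (a in calls) {
    for (b in calls) {
      got <- product_genotype(mk(a, b))$genotype
      want <- if (a == b) {
        a
      } else if (a == "N") {
        b
      } else if (b == "N") {
        a
      } else {
        "H"
      }
      expect_equal(got, want, info = paste(a, "vs", b))
    }
  }
})

test_that("noiseless reads reproduce simulated genotypes exactly across mechanisms", {
  assay <- toy_assay()
  set.seed(24)
  params <- clean_params(resection_mean = 150, invasion_extent_mean = 150)
  evs <- list(
    simulate_dsbr(params, assay$map, assay$break_site, 6),
    simulate_mr_nick(params, assay$map, assay$break_site$cut_center, 4),
    simulate_gap(params, assay$map, c(250, 330), 4),
    simulate_dloop_cleavage(params, assay$map, assay$break_site, 6)
  )
  offset <- 0
  for (ev in evs) {
    obs <- observe_colony(ev)
    bcs <- random_barcodes(nrow(ev))
    reads <- emit_reads(obs, assay$pair, assay$map, bcs, depth = 6, error_rate = 0)
    called <- call_events(reads, bcs, assay$pair, assay$map)
    g <- sim_genotypes(ev)
    for (i in seq_len(nrow(ev))) {
      row <- called[called$event_id == bcs$recombinant_id[i], ]
      expect_true(row$qc_pass)
      expect_equal(row$genotype_trunc[[1]], g$genotype_trunc[[i]])
      expect_equal(row$genotype_full[[1]], g$genotype_full[[i]])
    }
  }
})

test_that("per-marker genotype accuracy stays above 99% at 1% error and depth 20", {
  assay <- toy_assay()
  set.seed(25)
  ev <- simulate_dsbr(clean_params(resection_mean = 150), assay$map, assay$break_site, 15)
  obs <- observe_colony(ev)
  bcs <- random_barcodes(15)
  reads <- emit_reads(obs, assay$pair, assay$map, bcs, depth = 20, error_rate = 0.01)
  called <- call_events(reads, bcs, assay$pair, assay$map)
  g <- sim_genotypes(ev)
  n_mark <- nrow(tibble::as_tibble(assay$map))
  acc <- 0
  for (i in seq_len(nrow(ev))) {
    row <- called[called$event_id == bcs$recombinant_id[i], ]
    acc <- acc + sum(row$genotype_trunc[[1]] == g$genotype_trunc[[i]]) +
      sum(row$genotype_full[[1]] == g$genotype_full[[i]])
  }
  expect_gte(acc / (2 * n_mark * nrow(ev)), 0.99)
})
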