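test_that("segmentation collapses runs and absorbs or excludes N markers", {
  ta <- make_map(positions = seq(50, 300, by = 50), anchor = 175) # 6 markers
  seg <- segment_product(c("R", "R", "H", "H", "D", "D"), ta$map)
  expect_equal(seg$state, c("R", "H", "D"))
  expect_equal(seg$first_marker, c(1, 3, 5))
  expect_equal(seg$last_marker, c(2, 4, 6))

  # N between same-state neighbours is absorbed
  seg2 <- segment_product(c("R", "N", "R", "D", "D", "D"), ta$map)
  expect_equal(seg2$state, c("R", "D"))
  expect_equal(seg2$last_marker, c(3, 6))
  expect_equal(seg2$n_markers, c(3, 3))
  expect_length(attr(seg2, "excluded"), 0)

  # N between different states is excluded and reported
  seg3 <- segment_product(c("R", "R", "N", "D", "D", "D"), ta$map)
  expect_equal(seg3$state, c("R", "D"))
  expect_equal(attr(seg3, "excluded"), 3L)

  seg4 <- segment_product(rep("D", 6), ta$map)
  expect_equal(nrow(seg4), 1)
  expect_equal(seg4$n_markers, 6)

  expect_error(segment_product(rep("N", 6), ta$map), "all-N")
})

test_that("segmentation equals the linear-scan oracle on random vectors", {
  ta <- make_map(positions = seq(40, 400, by = 30), anchor = 220)
  pos <- tibble::as_tibble(ta$map)$pos_recipient
  set.seed(31)
  for (i in 1:1000) {
    g <- random_genotype(length(pos), p_n = 0.15)
    got <- segment_product(g, ta$map)
    want <- oracle_segments(g, pos)
    expect_equal(got$state, want$state)
    expect_equal(got$first_marker, want$first_marker)
    expect_equal(got$last_marker, want$last_marker)
  }
})

test_that("two-sided events yield asymmetric hetDNA tracts on opposite sides", {
  ta <- make_map(anchor = 225) # markers at 50..400, anchor 225
  gt <- c("R", "R", "H", "H", "D", "D", "D", "D")
  gf <- c("D", "D", "D", "D", "H", "H", "R", "R")
  tr <- event_tracts(gt, gf, ta$map, 225)
  het <- tr[tr$kind == "HETDNA", ]
  expect_equal(nrow(het), 2)
  expect_equal(het$side[het$product_id == "P_TRUNC"], "UPSTREAM")
  expect_equal(het$side[het$product_id == "P_FULL"], "DOWNSTREAM")
  expect_equal(unique(het$context), "RECIPIENT_DERIVED")
})

test_that("identical hetDNA positions in both products are symmetric", {
  ta <- make_map(anchor = 225)
  gt <- c("R", "R", "H", "H", "D", "D", "D", "D")
  gf <- c("D", "D", "H", "H", "R", "R", "R", "R")
  tr <- event_tracts(gt, gf, ta$map, 225)
  expect_equal(sort(unique(tr$kind[tr$first_marker == 3])), "SYMMETRIC_HETDNA")
  expect_equal(sum(tr$kind == "SYMMETRIC_HETDNA"), 2)
})

test_that("restoration patches interrupt hetDNA tracts", {
  ta <- make_map(anchor = 225)
  gt <- c("R", "H", "R", "H", "D", "D", "D", "D")
  gf <- c("D", "D", "D", "D", "H", "H", "R", "R")
  tr <- event_tracts(gt, gf, ta$map, 225)
  tt <- tr[tr$product_id == "P_TRUNC", ]
  expect_equal(tt$kind, c("HETDNA", "RESTORATION_PATCH", "HETDNA"))
  expect_equal(tt$first_marker, 2:4)
})

test_that("conversions are assigned by flank context, donor alterations included", {
  ta <- make_map(anchor = 225)
  # upstream D run in the truncated product is conversion in recipient context
  gt <- c("R", "R", "D", "H", "D", "D", "D", "D")
  gf <- c("D", "D", "D", "D", "H", "H", "R", "R")
  tr <- event_tracts(gt, gf, ta$map, 225)
  conv <- tr[tr$kind == "CONVERSION", ]
  expect_equal(conv$product_id, "P_TRUNC")
  expect_equal(conv$context, "RECIPIENT_DERIVED")
  expect_equal(conv$first_marker, 3)
  # R inside the full-length product's upstream donor flank is a donor alteration
  gf2 <- c("D", "R", "D", "D", "H", "H", "R", "R")
  tr2 <- event_tracts(gt, gf2, ta$map, 225)
  alt <- tr2[tr2$kind == "CONVERSION" & tr2$product_id == "P_FULL", ]
  expect_equal(alt$context, "DONOR_DERIVED")
})

test_that("hetDNA length uses the most break-distal transition midpoint", {
  ta <- make_map(anchor = 225) # markers at 50 * 1..8
  # H at markers 3-4 (150, 200): transition midpoint (100+150)/2 = 125
  gt <- c("R", "R", "H", "H", "D", "D", "D", "D")
  gf <- rep(c("D", "R"), c(4, 4))
  expect_equal(hetdna_length(gt, gf, ta$map, "UPSTREAM", 225), 100)
  expect_equal(hetdna_length(gt, gf, ta$map, "DOWNSTREAM", 225), 0)
  # tract reaching marker 1 extends to the homology border
  gt2 <- c("H", "H", "H", "H", "D", "D", "D", "D")
  expect_equal(hetdna_length(gt2, gf, ta$map, "UPSTREAM", 225), 225)
  # downstream side, H at markers 5-6 (250, 300): midpoint (300+350)/2 = 325
  gf3 <- c("D", "D", "D", "D", "H", "H", "R", "R")
  expect_equal(hetdna_length(gt, gf3, ta$map, "DOWNSTREAM", 225), 100)
  # conversion counts toward the transition (donor-vs-recipient boundary)
  gt3 <- c("R", "R", "D", "H", "D", "D", "D", "D")
  expect_equal(hetdna_length(gt3, gf, ta$map, "UPSTREAM", 225), 100)
})

test_that("total hetDNA length adds the two sides or uses the single one", {
  ta <- make_map(anchor = 225)
  gt <- c("R", "R", "H", "H", "D", "D", "D", "D")
  gf <- c("D", "D", "D", "D", "H", "H", "R", "R")
  up <- hetdna_length(gt, gf, ta$map, "UPSTREAM", 225)
  dn <- hetdna_length(gt, gf, ta$map, "DOWNSTREAM", 225)
  expect_equal(total_hetdna_length(gt, gf, ta$map, 225), up + dn)
  # one-sided event
  gf1 <- rep(c("D", "R"), c(4, 4))
  expect_equal(total_hetdna_length(gt, gf1, ta$map, 225), up)
  # full-homology two-sided event spans the whole homology region
  gt_full <- c("H", "H", "H", "H", "D", "D", "D", "D")
  gf_full <- c("D", "D", "D", "D", "H", "H", "H", "H")
  expect_equal(total_hetdna_length(gt_full, gf_full, ta$map, 225), 450)
  # no hetDNA at all is an error
  expect_error(
    total_hetdna_length(rep(c("R", "D"), c(4, 4)), gf1, ta$map, 225),
    "no hetDNA"
  )
})

test_that("side lengths are consistent with totals on random events", {
  assay <- full_assay()
  set.seed(32)
  ev <- simulate_dsbr(mechanism_params(p_back_migration = 0.3), assay$map, assay$break_site, 60)
  g <- sim_genotypes(ev)
  a <- assay$break_site$cut_center
  for (i in seq_len(nrow(g))) {
    gt <- g$genotype_trunc[[i]]
    gf <- g$genotype_full[[i]]
    up <- hetdna_length(gt, gf, assay$map, "UPSTREAM", a)
    dn <- hetdna_length(gt, gf, assay$map, "DOWNSTREAM", a)
    if (up + dn > 0) {
      tot <- total_hetdna_length(gt, gf, assay$map, a)
      expect_gte(up + dn, tot)
      if (up > 0 && dn > 0) expect_equal(up + dn, tot)
    }
  }
})

test_that("measured length deviates from the simulated extent by at most one interval", {
  assay <- full_assay()
  m <- tibble::as_tibble(assay$map)
  max_gap <- max(diff(m$pos_recipient))
  set.seed(33)
  ev <- simulate_dsbr(clean_params(), assay$map, assay$break_site, 60)
  g <- sim_genotypes(ev)
  a <- assay$break_site$cut_center
  span <- c(0, 4100)
  for (i in seq_len(nrow(g))) {
    up <- hetdna_length(g$genotype_trunc[[i]], g$genotype_full[[i]], assay$map, "UPSTREAM", a)
    dn <- hetdna_length(g$genotype_trunc[[i]], g$genotype_full[[i]], assay$map, "DOWNSTREAM", a)
    true_up <- min(ev$e_up[i], a - span[1])
    true_dn <- min(ev$e_dn[i], span[2] - a)
    expect_lte(abs(up - true_up), max_gap)
    expect_lte(abs(dn - true_dn), max_gap)
  }
})
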