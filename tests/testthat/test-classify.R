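test_that("induced classification follows the decision order on canonical patterns", {
  ta <- make_map(anchor = 225) # markers at 50 * 1..8
  classify1 <- function(gt, gf) classify_induced(gt, gf, ta$map, 225)

  # two-sided: upstream tract in the truncated product, downstream in the full
  two <- classify1(
    c("R", "R", "H", "H", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "H", "H", "R", "R")
  )
  expect_equal(two$klass, "TWO_SIDED")
  expect_true(two$hetdna_up && two$hetdna_dn)

  # one-sided left: hetDNA only upstream
  one <- classify1(
    c("R", "H", "H", "H", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "R", "R", "R", "R")
  )
  expect_equal(one$klass, "ONE_SIDED_LEFT")

  one_r <- classify1(
    c("R", "R", "R", "R", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "H", "H", "R", "R")
  )
  expect_equal(one_r$klass, "ONE_SIDED_RIGHT")

  # conversion-only: no hetDNA anywhere
  conv <- classify1(
    c("R", "R", "D", "D", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "R", "R", "R", "R")
  )
  expect_equal(conv$klass, "CONVERSION_ONLY")

  # donor-only: hetDNA exclusively in donor-derived context
  don <- classify1(
    c("R", "R", "R", "R", "D", "H", "D", "D"),
    c("D", "D", "D", "D", "R", "R", "R", "R")
  )
  expect_equal(don$klass, "DONOR_ONLY")
})

test_that("a displaced inter-product transition is recognized with its offset", {
  ta <- make_map(anchor = 225)
  # transition between markers 6 (300) and 7 (350): midpoint 325, 100 bp from
  # the break; the truncated product's tract spans the break
  cl <- classify_induced(
    c("H", "H", "H", "H", "H", "H", "D", "D"),
    c("D", "D", "D", "D", "D", "D", "H", "R"),
    ta$map, 225
  )
  expect_equal(cl$klass, "DISPLACED_TRANSITION")
  expect_equal(cl$displacement_bp, 100)
})

test_that("gap expansion features distinguish single-SNP and multi-SNP loss", {
  ta <- make_map(anchor = 225)
  # conversion at marker 5 only (the downstream break-flanking marker)
  f1 <- extract_features(
    c("R", "R", "H", "H", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "D", "H", "H", "R"),
    ta$map, 225
  )
  expect_equal(f1$gap_expansion_dn, "SINGLE_SNP")
  expect_equal(f1$gap_expansion_up, "NONE")
  # conversion spanning markers 5-7 is gap expansion
  f2 <- extract_features(
    c("R", "R", "H", "H", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "D", "D", "D", "H"),
    ta$map, 225
  )
  expect_equal(f2$gap_expansion_dn, "MULTI_SNP")
  # upstream single-SNP loss lives in the truncated product
  f3 <- extract_features(
    c("R", "R", "H", "D", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "H", "H", "R", "R"),
    ta$map, 225
  )
  expect_equal(f3$gap_expansion_up, "SINGLE_SNP")
})

test_that("interruption and donor-alteration features are counted", {
  ta <- make_map(anchor = 225)
  f <- extract_features(
    c("R", "H", "R", "H", "D", "D", "D", "D"), # restoration patch at marker 3
    c("D", "R", "D", "D", "H", "H", "R", "R"), # donor alteration at marker 2
    ta$map, 225
  )
  expect_equal(f$n_restoration_patches, 1)
  expect_equal(f$n_donor_alterations, 1)
  # interior conversion patch inside a hetDNA tract
  f2 <- extract_features(
    c("H", "H", "D", "H", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "H", "H", "R", "R"),
    ta$map, 225
  )
  expect_equal(f2$n_conversion_patches, 1)
})

test_that("terminal symmetric hetDNA is tagged terminal, interior symmetric interstitial", {
  assay <- full_assay()
  set.seed(41)
  ev <- simulate_dsbr(clean_params(p_hj_migration = 1, hj_migration_bp = 300), assay$map, assay$break_site, 40)
  g <- sim_genotypes(ev)
  feats <- purrr::map(seq_len(nrow(g)), function(i) {
    extract_features(g$genotype_trunc[[i]], g$genotype_full[[i]], assay$map, assay$break_site$cut_center)
  }) |> purrr::list_rbind()
  # junction migration converts tract ends to terminal symmetric hetDNA
  expect_gt(sum(feats$n_terminal_symmetric), 0)
  expect_equal(sum(feats$n_interstitial_symmetric), 0)
})

test_that("every event receives exactly one class (fuzz)", {
  ta <- make_map(positions = seq(40, 400, by = 40), anchor = 220)
  n_mark <- nrow(tibble::as_tibble(ta$map))
  set.seed(42)
  for (i in 1:1000) {
    gt <- random_genotype(n_mark, p_n = 0.1)
    gf <- random_genotype(n_mark, p_n = 0.1)
    cl <- classify_induced(gt, gf, ta$map, 220)
    expect_true(cl$klass %in% c(
      "TWO_SIDED", "ONE_SIDED_LEFT", "ONE_SIDED_RIGHT", "DISPLACED_TRANSITION",
      "DONOR_ONLY", "CONVERSION_ONLY", "UNINTERPRETABLE"
    ))
    # induced events never receive spontaneous-inference labels
    expect_false(cl$klass %in% c("NICK_LIKE", "GAP_LIKE"))
  }
})

test_that("spontaneous DSB patterns are inferred with break position and broken allele", {
  ta <- make_map(anchor = 225)
  # clean reciprocal transition at 225; recipient is the minor contributor
  inf <- infer_initiation(
    c("R", "R", "H", "H", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "H", "H", "R", "R"),
    ta$map
  )
  expect_equal(inf$klass, "TWO_SIDED")
  expect_equal(inf$lesion_type, "DSB")
  expect_equal(inf$inferred_position, 225)
  expect_equal(inf$inferred_allele, "RECIPIENT_D5")
  expect_equal(inf$in_3prime_half, FALSE)

  # an interstitial conversion tract between the two tracts relocates the
  # estimate to the conversion tract's center (markers 4-5: 200-250)
  inf2 <- infer_initiation(
    c("R", "R", "H", "D", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "D", "H", "R", "R"),
    ta$map
  )
  expect_equal(inf2$lesion_type, "DSB")
  expect_equal(inf2$inferred_position, 225)

  # donor-broken pattern: donor is the minor contributor
  inf3 <- infer_initiation(
    c("R", "R", "R", "R", "R", "H", "D", "D"),
    c("D", "D", "D", "D", "H", "R", "R", "R"),
    ta$map
  )
  expect_equal(inf3$klass, "TWO_SIDED")
  expect_equal(inf3$lesion_type, "DSB")
  expect_equal(inf3$inferred_allele, "DONOR_D3")
  expect_equal(inf3$inferred_position, 275)
  expect_equal(inf3$in_3prime_half, TRUE)
})

test_that("spontaneous nick and gap patterns are recognized", {
  ta <- make_map(anchor = 225)
  # nick: single asymmetric tract adjacent to the crossover point, donor side
  nick <- infer_initiation(
    c("R", "R", "R", "R", "H", "H", "D", "D"),
    c("D", "D", "D", "D", "R", "R", "R", "R")
  , ta$map)
  expect_equal(nick$klass, "NICK_LIKE")
  expect_equal(nick$lesion_type, "NICK")

  # gap: symmetric tract at the crossover point, asymmetric extension in one
  gap <- infer_initiation(
    c("R", "R", "R", "H", "H", "H", "D", "D"),
    c("D", "D", "D", "H", "H", "R", "R", "R")
  , ta$map)
  expect_equal(gap$klass, "GAP_LIKE")
  expect_equal(gap$lesion_type, "GAP")
  # position at the center of the symmetric block (markers 4-5: 200..250)
  expect_equal(gap$inferred_position, 225)

  # no hetDNA: conversion-only, indeterminate lesion
  none <- infer_initiation(
    c("R", "R", "D", "D", "D", "D", "D", "D"),
    c("D", "D", "D", "D", "R", "R", "R", "R")
  , ta$map)
  expect_equal(none$klass, "CONVERSION_ONLY")
  expect_equal(none$lesion_type, "INDETERMINATE")
})

test_that("simulated mechanisms are classified in full agreement with truth", {
  assay <- full_assay()
  set.seed(43)
  bs <- assay$break_site
  regimes <- list(
    clean = simulate_dsbr(clean_params(), assay$map, bs, 80),
    back_migration = simulate_dsbr(clean_params(p_back_migration = 1), assay$map, bs, 80),
    complexity = simulate_dsbr(
      mechanism_params(p_end_loss = 0.3, p_patch_repair = 0.1, p_template_switch = 0.2),
      assay$map, bs, 80
    )
  )
  for (nm in names(regimes)) {
    ev <- regimes[[nm]]
    cl <- classify_events(sim_genotypes(ev), assay$map, bs)
    expect_equal(cl$klass, ev$truth_class, info = nm)
  }
  # spontaneous mechanisms through initiation inference
  evn <- simulate_mr_nick(clean_params(), assay$map, 2007, 60)
  expect_equal(
    classify_events(sim_genotypes(evn), assay$map, NULL)$klass,
    evn$truth_class
  )
  evg <- simulate_gap(clean_params(), assay$map, c(1950, 2100), 60)
  expect_equal(
    classify_events(sim_genotypes(evg), assay$map, NULL)$klass,
    evg$truth_class
  )
  evd <- simulate_dloop_cleavage(clean_params(), assay$map, bs, 60)
  expect_equal(
    classify_events(sim_genotypes(evd), assay$map, bs)$klass,
    evd$truth_class
  )
})

test_that("inferred break positions land within one inter-marker interval", {
  assay <- full_assay()
  m <- tibble::as_tibble(assay$map)
  max_gap <- max(diff(m$pos_recipient))
  set.seed(44)
  pos <- runif(100, 300, 3800)
  ev <- simulate_dsbr(clean_params(), assay$map, pos, 100)
  inf <- classify_events(sim_genotypes(ev), assay$map, NULL)
  ok <- inf$klass == "TWO_SIDED" & abs(inf$inferred_position - ev$x0) <= max_gap
  expect_gte(mean(ok), 0.95)
})
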