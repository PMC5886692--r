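# Strand-resolved simulator of crossover-forming repair mechanisms.
#
# Events are simulated at marker resolution with bp-valued interval
# endpoints: each product duplex is a 2 x M matrix of parental alleles
# ("R"/"D"), one row per strand. Sequence-level realization happens only in
# emit_reads(). Every sampled quantity is recorded in the truth columns so an
# event can be replayed (replay audit) and compared against classifier calls.

#' Mechanism simulation parameters
#'
#' Collects the knobs of the repair-mechanism models. Extent arguments accept
#' either a single number (the mean of a floored geometric distribution) or a
#' `function(n)` returning `n` sampled bp values.
#'
#' @param resection_mean Mean bp of hetDNA extent per side formed by strand
#'   invasion / second-end capture (floored geometric).
#' @param extent_min Floor (bp) applied to geometric extents, so that a
#'   canonical event always reaches at least the break-flanking marker.
#' @param p_end_loss Probability per side that the 3' end is lost, expanding
#'   the break into a gap (break-adjacent conversion tract).
#' @param end_loss_mean Mean bp of the gap expansion.
#' @param end_loss_min Floor (bp) of the gap expansion.
#' @param p_single_snp_loss_upstream,p_single_snp_loss_downstream
#'   Probability that the break-adjacent marker on that side is removed
#'   (polymerase proofreading of the terminal mismatch) when no multi-marker
#'   gap expansion occurred on the side. Defaults are the observed
#'   efficiencies 0.49 upstream and 0.94 downstream.
#' @param invasion_extent_mean Mean bp of the single invasion tract used by
#'   the nick, gap and D-loop-cleavage models.
#' @param p_back_migration Probability the back end of the D-loop migrates to
#'   the break before second-end extension, erasing invasion-side hetDNA.
#' @param hj_migration_bp Signed Holliday-junction migration (bp): a single
#'   number or `function(n)`. Positive values convert the distal `hj` bp of
#'   one tract into terminal symmetric hetDNA; negative values displace the
#'   inter-product hetDNA transition from the break by `|hj|` bp upstream.
#' @param p_hj_migration Probability that junction migration occurs at all.
#' @param p_template_switch Probability of a single sister-template excursion
#'   during fill-in synthesis, producing an interstitial donor-context
#'   hetDNA tract.
#' @param switch_extent_mean Mean bp of the template-switch excursion.
#' @param resolution_mode `"NICK_DIRECTED"` (hetDNA always upstream in the
#'   doubly-truncated product and downstream in the full-length product) or
#'   `"RANDOM_LIGATED"` (orientation flipped with probability 0.5).
#' @param p_patch_repair Per-mismatch probability of MMR-independent repair
#'   within hetDNA.
#' @param p_restoration_given_repair Probability a repaired mismatch restores
#'   the original allele rather than converting it (default 26/37).
#' @param p_daughter_loss Probability that only one post-replication lineage
#'   of a product is recovered in the colony.
#' @return A list of class `mechanism_params`.
#' @export
mechanism_params <- function(resection_mean = 1000,
                             extent_min = 60,
                             p_end_loss = 0.15,
                             end_loss_mean = 150,
                             end_loss_min = 30,
                             p_single_snp_loss_upstream = 0.49,
                             p_single_snp_loss_downstream = 0.94,
                             invasion_extent_mean = 1000,
                             p_back_migration = 0,
                             hj_migration_bp = 0,
                             p_hj_migration = 0,
                             p_template_switch = 0,
                             switch_extent_mean = 200,
                             resolution_mode = c("NICK_DIRECTED", "RANDOM_LIGATED"),
                             p_patch_repair = 0,
                             p_restoration_given_repair = 26 / 37,
                             p_daughter_loss = 0) {
  resolution_mode <- match.arg(resolution_mode)
  p <- list(
    resection_mean = resection_mean, extent_min = extent_min,
    p_end_loss = p_end_loss, end_loss_mean = end_loss_mean,
    end_loss_min = end_loss_min,
    p_single_snp_loss_upstream = p_single_snp_loss_upstream,
    p_single_snp_loss_downstream = p_single_snp_loss_downstream,
    invasion_extent_mean = invasion_extent_mean,
    p_back_migration = p_back_migration,
    hj_migration_bp = hj_migration_bp, p_hj_migration = p_hj_migration,
    p_template_switch = p_template_switch,
    switch_extent_mean = switch_extent_mean,
    resolution_mode = resolution_mode,
    p_patch_repair = p_patch_repair,
    p_restoration_given_repair = p_restoration_given_repair,
    p_daughter_loss = p_daughter_loss
  )
  probs <- p[grepl("^p_", names(p))]
  stopifnot(all(vapply(probs, function(x) x >= 0 && x <= 1, logical(1))))
  structure(p, class = "mechanism_params")
}

#' Clean canonical parameter preset
#'
#' All optional complexity off: no end loss, no single-SNP loss, no
#' migration, switching, repair or daughter loss. Canonical events are then
#' observably two-sided with the stereotyped orientation.
#'
#' @param ... Overrides passed to [mechanism_params()].
#' @return A `mechanism_params`.
#' @export
clean_params <- function(...) {
  defaults <- list(
    p_end_loss = 0, p_single_snp_loss_upstream = 0,
    p_single_snp_loss_downstream = 0, p_back_migration = 0,
    p_hj_migration = 0, p_template_switch = 0, p_patch_repair = 0,
    p_daughter_loss = 0
  )
  do.call(mechanism_params, utils::modifyList(defaults, list(...)))
}

sample_extent <- function(spec, n, minimum) {
  if (is.function(spec)) {
    return(pmax(0, spec(n)))
  }
  if (spec <= minimum) {
    return(rep(minimum, n))
  }
  minimum + rgeom(n, 1 / (spec - minimum + 1))
}

map_positions <- function(map) as_tibble(map)$pos_recipient

map_span <- function(map) attr(map, "homology_span") %||% c(0, max(map_positions(map)) + 1)

# Markers (indices) with pos in half-open [start, end)
markers_in <- function(pos, start, end) which(pos >= start & pos < end)

flip_allele <- function(x) ifelse(x == "R", "D", "R")

# Build one product duplex from a flank/interval description.
# intervals: list of list(start, end, type = "het"|"conv", allele = for conv)
build_duplex <- function(pos, flank_left, flank_right, boundary, intervals) {
  base <- ifelse(pos < boundary, flank_left, flank_right)
  s1 <- base
  s2 <- base
  for (iv in intervals) {
    idx <- markers_in(pos, iv$start, iv$end)
    if (length(idx) == 0) next
    if (iv$type == "conv") {
      s1[idx] <- iv$allele
      s2[idx] <- iv$allele
    } else {
      s2[idx] <- flip_allele(s1[idx])
    }
  }
  rbind(s1, s2)
}

apply_repairs <- function(duplex, repairs, product) {
  if (is.null(repairs) || nrow(repairs) == 0) {
    return(duplex)
  }
  rr <- repairs[repairs$product == product, , drop = FALSE]
  for (i in seq_len(nrow(rr))) {
    j <- rr$marker[i]
    duplex[, j] <- rr$to[i]
  }
  duplex
}

# ---------------------------------------------------------------------------
# DSBR (canonical double-strand break repair, with optional complexity)
# ---------------------------------------------------------------------------

#' Simulate crossover events under the canonical DSB repair mechanism
#'
#' Per event: hetDNA extents are sampled on each side of the break; optional
#' 3'-end loss converts break-adjacent hetDNA into a conversion tract (gap
#' expansion); the break-adjacent marker may additionally be removed with
#' side-specific probabilities; optional back-migration erases the
#' invasion-side tract; optional junction migration creates terminal
#' symmetric hetDNA or displaces the inter-product transition; an optional
#' template switch adds an interstitial donor-context tract; mismatches may
#' be patch-repaired with a restoration bias; resolution orientation follows
#' `resolution_mode`.
#'
#' @param params A [mechanism_params()].
#' @param map A `marker_map`.
#' @param brk A `break_site`, or a numeric break position (spontaneous mode);
#'   may be a vector of length `n` to vary the initiation site per event.
#' @param n Number of events.
#' @return A tibble of class `sim_events`: one row per event with truth
#'   columns and list-columns `duplex_trunc` / `duplex_full` (2 x M allele
#'   matrices, one row per strand).
#' @export
simulate_dsbr <- function(params, map, brk, n) {
  stopifnot(inherits(params, "mechanism_params"))
  pos <- map_positions(map)
  span <- map_span(map)
  x0 <- if (inherits(brk, "break_site")) rep(brk$cut_center, n) else rep_len(as.numeric(brk), n)
  if (any(x0 < span[1] | x0 >= span[2])) stop("break outside homology", call. = FALSE)

  e_up <- pmin(sample_extent(params$resection_mean, n, params$extent_min), x0 - span[1])
  e_dn <- pmin(sample_extent(params$resection_mean, n, params$extent_min), span[2] - x0)
  loss_up <- ifelse(
    runif(n) < params$p_end_loss,
    pmin(sample_extent(params$end_loss_mean, n, params$end_loss_min), e_up), 0
  )
  loss_dn <- ifelse(
    runif(n) < params$p_end_loss,
    pmin(sample_extent(params$end_loss_mean, n, params$end_loss_min), e_dn), 0
  )
  back <- runif(n) < params$p_back_migration
  back_side <- ifelse(back, ifelse(runif(n) < 0.5, "UPSTREAM", "DOWNSTREAM"), NA)
  hj <- ifelse(runif(n) < params$p_hj_migration,
    if (is.function(params$hj_migration_bp)) params$hj_migration_bp(n) else rep(params$hj_migration_bp, n),
    0
  )
  hj_side <- ifelse(hj > 0, ifelse(runif(n) < 0.5, "UPSTREAM", "DOWNSTREAM"), NA)
  ts <- runif(n) < params$p_template_switch
  ts_len <- sample_extent(params$switch_extent_mean, n, 30)
  flipped <- if (params$resolution_mode == "RANDOM_LIGATED") runif(n) < 0.5 else rep(FALSE, n)

  events <- vector("list", n)
  for (i in seq_len(n)) {
    # single-SNP loss applies only without multi-marker gap expansion on the side
    fm_up <- max(which(pos < x0[i]), -Inf)
    fm_dn <- min(which(pos >= x0[i]), Inf)
    multi_up <- length(markers_in(pos, x0[i] - loss_up[i], x0[i])) >= 2
    multi_dn <- length(markers_in(pos, x0[i], x0[i] + loss_dn[i])) >= 2
    snp_up <- !multi_up && is.finite(fm_up) &&
      runif(1) < params$p_single_snp_loss_upstream
    snp_dn <- !multi_dn && is.finite(fm_dn) &&
      runif(1) < params$p_single_snp_loss_downstream

    ts_iv <- c(NA_real_, NA_real_)
    if (ts[i]) {
      # excursion within the donor-templated fill-in region downstream of the
      # break, inside the donor-derived flank of the product that inherits it
      lo <- x0[i] + 20
      hi <- min(span[2] - 20, x0[i] + 1500)
      if (hi - lo > ts_len[i]) {
        st <- runif(1, lo, hi - ts_len[i])
        ts_iv <- c(st, st + ts_len[i])
      }
    }

    truth <- list(
      mechanism = "DSBR", x0 = x0[i],
      e_up = e_up[i], e_dn = e_dn[i],
      loss_up = loss_up[i], loss_dn = loss_dn[i],
      snp_up = snp_up, snp_dn = snp_dn,
      back_side = back_side[i], hj_bp = hj[i], hj_side = hj_side[i],
      ts_start = ts_iv[1], ts_end = ts_iv[2],
      flipped = flipped[i]
    )
    dup <- replay_dsbr(truth, map)
    # patch repair sampled on realized hetDNA markers
    repairs <- sample_repairs(dup, params)
    dup$duplex_trunc <- apply_repairs(dup$duplex_trunc, repairs, "P_TRUNC")
    dup$duplex_full <- apply_repairs(dup$duplex_full, repairs, "P_FULL")
    truth$repairs <- list(repairs)
    events[[i]] <- c(truth, list(
      duplex_trunc = list(dup$duplex_trunc),
      duplex_full = list(dup$duplex_full)
    ))
  }
  finish_events(events, map)
}

# Rebuild the two product duplexes of a DSBR event from its truth record
# (before patch repair). Used both for construction and the replay audit.
replay_dsbr <- function(truth, map) {
  pos <- map_positions(map)
  x0 <- truth$x0
  t_trans <- if (!is.na(truth$hj_side) || truth$hj_bp >= 0) x0 else x0 + truth$hj_bp

  up_ivs <- list() # intervals in the upstream-tract carrier
  dn_ivs <- list()
  e_up <- truth$e_up
  e_dn <- truth$e_dn
  if (identical(truth$back_side, "UPSTREAM")) e_up <- 0
  if (identical(truth$back_side, "DOWNSTREAM")) e_dn <- 0

  # conversions stay with the recipient-context product on each side
  conv_up <- list()
  conv_dn <- list()
  if (truth$loss_up > 0) {
    conv_up <- c(conv_up, list(list(start = x0 - truth$loss_up, end = x0, type = "conv", allele = "D")))
  }
  if (truth$loss_dn > 0) {
    conv_dn <- c(conv_dn, list(list(start = x0, end = x0 + truth$loss_dn, type = "conv", allele = "D")))
  }
  if (isTRUE(truth$snp_up)) {
    fm <- max(pos[pos < x0])
    conv_up <- c(conv_up, list(list(start = fm, end = fm + 1, type = "conv", allele = "D")))
  }
  if (isTRUE(truth$snp_dn)) {
    fm <- min(pos[pos >= x0])
    conv_dn <- c(conv_dn, list(list(start = fm, end = fm + 1, type = "conv", allele = "D")))
  }

  het_up <- list(start = x0 - e_up, end = min(t_trans, x0 - truth$loss_up), type = "het")
  # under a displaced transition (t < x0) the downstream product's tract
  # begins at the transition, not at the break
  dn_start <- if (t_trans < x0) t_trans else max(t_trans, x0 + truth$loss_dn)
  het_dn <- list(start = dn_start, end = x0 + e_dn, type = "het")

  sym_iv <- NULL
  if (!is.na(truth$hj_side) && truth$hj_bp > 0) {
    # terminal symmetric hetDNA at the break-distal end of one tract
    if (truth$hj_side == "UPSTREAM" && e_up > 0) {
      sym_iv <- list(start = het_up$start, end = min(het_up$start + truth$hj_bp, x0), type = "het")
    } else if (truth$hj_side == "DOWNSTREAM" && e_dn > 0) {
      sym_iv <- list(start = max(het_dn$end - truth$hj_bp, x0), end = het_dn$end, type = "het")
    }
  }
  ts_iv <- NULL
  if (!is.na(truth$ts_start)) {
    ts_iv <- list(start = truth$ts_start, end = truth$ts_end, type = "het")
  }

  # carrier assignment: canonical (unflipped) puts the upstream tract in
  # P_TRUNC (recipient flank upstream / donor flank downstream) and the
  # downstream tract in P_FULL
  trunc_ivs <- c(conv_up, list(het_up))
  full_ivs <- c(conv_dn, list(het_dn))
  if (isTRUE(truth$flipped)) {
    # orientation flipped: the tracts swap carriers and land in donor-context
    trunc_ivs <- c(conv_up, list(het_dn))
    full_ivs <- c(conv_dn, list(het_up))
  }
  # template switch: interstitial donor-context tract in the product whose
  # donor flank was synthesized during fill-in (downstream flank = P_TRUNC)
  if (!is.null(ts_iv)) trunc_ivs <- c(trunc_ivs, list(ts_iv))
  # terminal symmetric hetDNA appears additionally in the partner product
  if (!is.null(sym_iv)) {
    if (truth$hj_side == "UPSTREAM") full_ivs <- c(full_ivs, list(sym_iv)) else trunc_ivs <- c(trunc_ivs, list(sym_iv))
  }

  list(
    duplex_trunc = build_duplex(pos, "R", "D", t_trans, trunc_ivs),
    duplex_full = build_duplex(pos, "D", "R", t_trans, full_ivs)
  )
}

sample_repairs <- function(dup, params) {
  out <- tibble(product = character(), marker = integer(), to = character(), outcome = character())
  if (params$p_patch_repair <= 0) {
    return(out)
  }
  for (product in c("P_TRUNC", "P_FULL")) {
    d <- if (product == "P_TRUNC") dup$duplex_trunc else dup$duplex_full
    het <- which(d[1, ] != d[2, ])
    if (length(het) == 0) next
    rep_idx <- het[runif(length(het)) < params$p_patch_repair]
    if (length(rep_idx) == 0) next
    restore <- runif(length(rep_idx)) < params$p_restoration_given_repair
    # restoration returns the context allele; the context allele is the one
    # the first strand carried before invasion flipped the second strand
    to <- ifelse(restore, d[1, rep_idx], d[2, rep_idx])
    out <- bind_rows(out, tibble(
      product = product, marker = rep_idx, to = to,
      outcome = ifelse(restore, "RESTORATION", "CONVERSION")
    ))
  }
  out
}

# ---------------------------------------------------------------------------
# Nick (Meselson-Radding), gap, and D-loop-cleavage mechanisms
# ---------------------------------------------------------------------------

#' Simulate nick-initiated (Meselson-Radding) crossover events
#'
#' A single asymmetric hetDNA tract forms in donor-derived context adjacent
#' to the crossover point, in one product only.
#'
#' @inheritParams simulate_dsbr
#' @param nick_position Recipient-frame bp position(s) of the initiating
#'   nick (recycled to length `n`).
#' @return A `sim_events` tibble.
#' @export
simulate_mr_nick <- function(params, map, nick_position, n) {
  stopifnot(inherits(params, "mechanism_params"))
  pos <- map_positions(map)
  span <- map_span(map)
  p <- rep_len(as.numeric(nick_position), n)
  if (any(p < span[1] | p >= span[2])) stop("nick outside homology", call. = FALSE)
  ext <- sample_extent(params$invasion_extent_mean, n, params$extent_min)
  dir_dn <- runif(n) < 0.5

  events <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- list(
      mechanism = "MR_NICK", x0 = p[i],
      e_up = if (dir_dn[i]) 0 else min(ext[i], p[i] - span[1]),
      e_dn = if (dir_dn[i]) min(ext[i], span[2] - p[i]) else 0,
      loss_up = 0, loss_dn = 0, snp_up = FALSE, snp_dn = FALSE,
      back_side = NA_character_, hj_bp = 0, hj_side = NA_character_,
      ts_start = NA_real_, ts_end = NA_real_, flipped = FALSE,
      repairs = list(tibble(
        product = character(), marker = integer(),
        to = character(), outcome = character()
      ))
    )
    dup <- replay_mr_nick(truth, map)
    events[[i]] <- c(truth, list(
      duplex_trunc = list(dup$duplex_trunc),
      duplex_full = list(dup$duplex_full)
    ))
  }
  finish_events(events, map)
}

replay_mr_nick <- function(truth, map) {
  pos <- map_positions(map)
  p <- truth$x0
  if (truth$e_dn > 0) {
    # tract in the downstream donor flank, carried by the truncated product
    tr <- list(list(start = p, end = p + truth$e_dn, type = "het"))
    list(
      duplex_trunc = build_duplex(pos, "R", "D", p, tr),
      duplex_full = build_duplex(pos, "D", "R", p, list())
    )
  } else {
    # tract in the upstream donor flank, carried by the full-length product
    tr <- list(list(start = p - truth$e_up, end = p, type = "het"))
    list(
      duplex_trunc = build_duplex(pos, "R", "D", p, list()),
      duplex_full = build_duplex(pos, "D", "R", p, tr)
    )
  }
}

#' Simulate gap-initiated crossover events
#'
#' Symmetric hetDNA forms across the gap interval in both products, with an
#' asymmetric extension beyond the gap in exactly one product. A zero-length
#' gap degenerates to the nick pattern.
#'
#' @inheritParams simulate_dsbr
#' @param gap_interval Numeric length-2 vector `c(start, end)` of the gap, or
#'   an `n` x 2 matrix.
#' @return A `sim_events` tibble.
#' @export
simulate_gap <- function(params, map, gap_interval, n) {
  stopifnot(inherits(params, "mechanism_params"))
  pos <- map_positions(map)
  span <- map_span(map)
  g <- if (is.matrix(gap_interval)) gap_interval else matrix(rep(gap_interval, each = n), ncol = 2)
  if (any(g[, 1] < span[1] | g[, 2] > span[2] | g[, 1] > g[, 2])) {
    stop("gap outside homology", call. = FALSE)
  }
  ext <- sample_extent(params$invasion_extent_mean, n, params$extent_min)
  dir_dn <- runif(n) < 0.5

  events <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- list(
      mechanism = "GAP", x0 = (g[i, 1] + g[i, 2]) / 2,
      e_up = if (dir_dn[i]) 0 else min(ext[i], g[i, 1] - span[1]),
      e_dn = if (dir_dn[i]) min(ext[i], span[2] - g[i, 2]) else 0,
      loss_up = 0, loss_dn = 0, snp_up = FALSE, snp_dn = FALSE,
      back_side = NA_character_, hj_bp = 0, hj_side = NA_character_,
      ts_start = g[i, 1], ts_end = g[i, 2], # reused: symmetric interval
      flipped = FALSE,
      repairs = list(tibble(
        product = character(), marker = integer(),
        to = character(), outcome = character()
      ))
    )
    dup <- replay_gap(truth, map)
    events[[i]] <- c(truth, list(
      duplex_trunc = list(dup$duplex_trunc),
      duplex_full = list(dup$duplex_full)
    ))
  }
  finish_events(events, map)
}

replay_gap <- function(truth, map) {
  pos <- map_positions(map)
  g1 <- truth$ts_start
  g2 <- truth$ts_end
  sym <- list(start = g1, end = g2, type = "het")
  if (truth$e_dn > 0) {
    trunc_ivs <- list(sym, list(start = g2, end = g2 + truth$e_dn, type = "het"))
    full_ivs <- list(sym)
  } else {
    trunc_ivs <- list(sym)
    full_ivs <- list(sym, list(start = g1 - truth$e_up, end = g1, type = "het"))
  }
  list(
    duplex_trunc = build_duplex(pos, "R", "D", g1, trunc_ivs),
    duplex_full = build_duplex(pos, "D", "R", g2, full_ivs)
  )
}

#' Simulate D-loop-cleavage crossover events
#'
#' The invaded donor is nicked at both D-loop edges before the invading end
#' is extended, creating one crossover product carrying the invasion-side
#' hetDNA; the reciprocal product is completed by an SDSA-like annealing
#' whose extended end is chosen at random. Extension of the broken-recipient
#' end yields one-sided hetDNA; extension of the donor end yields a pattern
#' indistinguishable from canonical two-sided repair.
#'
#' @inheritParams simulate_dsbr
#' @return A `sim_events` tibble with an `extended_end` truth column
#'   (`"RECIPIENT"` or `"DONOR"`).
#' @export
simulate_dloop_cleavage <- function(params, map, brk, n) {
  stopifnot(inherits(params, "mechanism_params"))
  pos <- map_positions(map)
  span <- map_span(map)
  x0 <- if (inherits(brk, "break_site")) rep(brk$cut_center, n) else rep_len(as.numeric(brk), n)
  e1 <- pmin(sample_extent(params$invasion_extent_mean, n, params$extent_min), x0 - span[1])
  e2 <- pmin(sample_extent(params$invasion_extent_mean, n, params$extent_min), span[2] - x0)
  ext_donor <- runif(n) < 0.5

  events <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- list(
      mechanism = "DLOOP_CLEAVAGE", x0 = x0[i],
      e_up = e1[i], e_dn = if (ext_donor[i]) e2[i] else 0,
      loss_up = 0, loss_dn = 0, snp_up = FALSE, snp_dn = FALSE,
      back_side = NA_character_, hj_bp = 0, hj_side = NA_character_,
      ts_start = NA_real_, ts_end = NA_real_, flipped = FALSE,
      extended_end = if (ext_donor[i]) "DONOR" else "RECIPIENT",
      repairs = list(tibble(
        product = character(), marker = integer(),
        to = character(), outcome = character()
      ))
    )
    dup <- replay_dloop(truth, map)
    events[[i]] <- c(truth, list(
      duplex_trunc = list(dup$duplex_trunc),
      duplex_full = list(dup$duplex_full)
    ))
  }
  finish_events(events, map)
}

replay_dloop <- function(truth, map) {
  pos <- map_positions(map)
  x0 <- truth$x0
  trunc_ivs <- list(list(start = x0 - truth$e_up, end = x0, type = "het"))
  full_ivs <- if (truth$e_dn > 0) {
    list(list(start = x0, end = x0 + truth$e_dn, type = "het"))
  } else {
    list()
  }
  list(
    duplex_trunc = build_duplex(pos, "R", "D", x0, trunc_ivs),
    duplex_full = build_duplex(pos, "D", "R", x0, full_ivs)
  )
}

# ---------------------------------------------------------------------------
# Event assembly, truth labels, replay audit
# ---------------------------------------------------------------------------

finish_events <- function(events, map) {
  ev <- purrr::map(events, function(e) {
    miss <- setdiff("extended_end", names(e))
    if (length(miss)) e$extended_end <- NA_character_
    tibble(
      mechanism = e$mechanism, x0 = e$x0, e_up = e$e_up, e_dn = e$e_dn,
      loss_up = e$loss_up, loss_dn = e$loss_dn,
      snp_up = e$snp_up, snp_dn = e$snp_dn,
      back_side = e$back_side %||% NA_character_,
      hj_bp = e$hj_bp, hj_side = e$hj_side %||% NA_character_,
      ts_start = e$ts_start, ts_end = e$ts_end,
      flipped = e$flipped, extended_end = e$extended_end,
      repairs = e$repairs,
      duplex_trunc = e$duplex_trunc, duplex_full = e$duplex_full
    )
  }) |> list_rbind()
  ev <- mutate(ev, event_id = row_number(), .before = 1)
  ev$truth_class <- truth_classes(ev, map)
  structure(ev, map = map, class = c("sim_events", class(ev)))
}

# Marker-level truth label per event, computed directly from the duplexes and
# the recorded anchor/transition (not via the classifier's segmentation).
truth_classes <- function(events, map) {
  pos <- map_positions(map)
  vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    dt <- e$duplex_trunc[[1]]
    df <- e$duplex_full[[1]]
    het_t <- pos[dt[1, ] != dt[2, ]]
    het_f <- pos[df[1, ] != df[2, ]]
    x0 <- e$x0
    if (length(het_t) == 0 && length(het_f) == 0) {
      return("CONVERSION_ONLY")
    }
    if (e$mechanism == "MR_NICK") {
      return("NICK_LIKE")
    }
    if (e$mechanism == "GAP") {
      sym <- intersect(het_t, het_f)
      asym_t <- setdiff(het_t, het_f)
      asym_f <- setdiff(het_f, het_t)
      if (length(sym) > 0 && xor(length(asym_t) > 0, length(asym_f) > 0)) {
        return("GAP_LIKE")
      }
      if (length(sym) > 0 && length(asym_t) == 0 && length(asym_f) == 0) {
        return("UNINTERPRETABLE")
      }
      return("NICK_LIKE")
    }
    if (isTRUE(e$flipped)) {
      return("DONOR_ONLY")
    }
    # unflipped: recipient-context hetDNA lives at positions < transition in
    # the truncated product and >= transition in the full-length product
    t_trans <- if (!is.na(e$hj_side) || e$hj_bp >= 0) x0 else x0 + e$hj_bp
    rc_t <- het_t[het_t < t_trans]
    rc_f <- het_f[het_f >= t_trans]
    displaced <- sum(pos > min(x0, t_trans) & pos < max(x0, t_trans)) >= 1
    if (displaced && length(rc_t) > 0 && length(rc_f) > 0) {
      return("DISPLACED_TRANSITION")
    }
    up_t <- any(rc_t < x0)
    dn_t <- any(rc_t >= x0)
    up_f <- any(rc_f < x0)
    dn_f <- any(rc_f >= x0)
    if ((up_t || up_f) && (dn_t || dn_f)) {
      # two-sided only when the sides sit in different products; a single
      # product carrying hetDNA on both sides of the break is not a
      # recognizable pattern
      if ((up_t && dn_f) || (up_f && dn_t)) {
        return("TWO_SIDED")
      }
      return("UNINTERPRETABLE")
    }
    if (up_t || up_f) {
      return("ONE_SIDED_LEFT")
    }
    if (dn_t || dn_f) {
      return("ONE_SIDED_RIGHT")
    }
    "DONOR_ONLY" # remaining hetDNA sits in donor-derived context only
  }, character(1))
}

#' Replay audit: rebuild every event's duplexes from its truth record
#'
#' @param events A `sim_events` tibble.
#' @return Logical vector: `TRUE` where the stored duplexes equal the
#'   replayed ones (patch repairs re-applied from the truth record).
#' @export
replay_audit <- function(events) {
  map <- attr(events, "map")
  vapply(seq_len(nrow(events)), function(i) {
    e <- as.list(events[i, ])
    e$repairs <- events$repairs[[i]]
    dup <- switch(e$mechanism,
      DSBR = replay_dsbr(e, map),
      MR_NICK = replay_mr_nick(e, map),
      GAP = replay_gap(e, map),
      DLOOP_CLEAVAGE = replay_dloop(e, map)
    )
    dup$duplex_trunc <- apply_repairs(dup$duplex_trunc, e$repairs, "P_TRUNC")
    dup$duplex_full <- apply_repairs(dup$duplex_full, e$repairs, "P_FULL")
    identical(unname(dup$duplex_trunc), unname(events$duplex_trunc[[i]])) &&
      identical(unname(dup$duplex_full), unname(events$duplex_full[[i]]))
  }, logical(1))
}

#' Observable orientation of a two-sided event
#'
#' Which product carries the upstream hetDNA tract: `"canonical"` when the
#' doubly-truncated product holds the upstream tract and the full-length
#' product the downstream tract, `"flipped"` for the reverse, `NA` when the
#' event is not observably two-sided.
#'
#' @param events A `sim_events` tibble.
#' @return Character vector.
#' @export
event_orientation <- function(events) {
  map <- attr(events, "map")
  pos <- map_positions(map)
  vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    het_t <- pos[e$duplex_trunc[[1]][1, ] != e$duplex_trunc[[1]][2, ]]
    het_f <- pos[e$duplex_full[[1]][1, ] != e$duplex_full[[1]][2, ]]
    x0 <- e$x0
    if (any(het_t < x0) && any(het_f >= x0) && !any(het_t >= x0) && !any(het_f < x0)) {
      return("canonical")
    }
    if (any(het_t >= x0) && any(het_f < x0) && !any(het_t < x0) && !any(het_f >= x0)) {
      return("flipped")
    }
    NA_character_
  }, character(1))
}

# ---------------------------------------------------------------------------
# Colony observation and read emission
# ---------------------------------------------------------------------------

#' Segregate simulated product duplexes into colony species
#'
#' Each product duplex replicates into its two strand-faithful lineages; a
#' duplex with at least one mismatched marker yields two consensus species
#' unless daughter loss drops one lineage (hetDNA then becomes invisible and
#' the product can appear as pure conversion).
#'
#' @param events A `sim_events` tibble.
#' @param p_daughter_loss Probability that only one lineage of a product is
#'   recovered.
#' @return A tibble with one row per (event, product, species): columns
#'   `event_id`, `product_id`, `species`, `profile` (list of allele vectors).
#' @export
observe_colony <- function(events, p_daughter_loss = 0) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    for (product in c("P_TRUNC", "P_FULL")) {
      d <- if (product == "P_TRUNC") events$duplex_trunc[[i]] else events$duplex_full[[i]]
      lineages <- list(unname(d[1, ]), unname(d[2, ]))
      if (runif(1) < p_daughter_loss) {
        lineages <- lineages[sample(2, 1)]
      } else if (identical(lineages[[1]], lineages[[2]])) {
        lineages <- lineages[1]
      }
      for (j in seq_along(lineages)) {
        rows[[length(rows) + 1]] <- tibble(
          event_id = events$event_id[i], product_id = product,
          species = j, profile = list(lineages[[j]])
        )
      }
    }
  }
  list_rbind(rows)
}

#' Convert simulated events directly to product genotype vectors
#'
#' Shortcut for noiseless round trips: applies [observe_colony()] and the
#' hetDNA diagnosis (two species differing at a marker = H) without read
#' emission.
#'
#' @inheritParams observe_colony
#' @return A tibble with `event_id`, `genotype_trunc`, `genotype_full`
#'   (list-columns of per-marker calls in `{R, D, H}`).
#' @export
sim_genotypes <- function(events, p_daughter_loss = 0) {
  obs <- observe_colony(events, p_daughter_loss)
  combine <- function(profiles) {
    if (length(profiles) == 1) {
      return(profiles[[1]])
    }
    a <- profiles[[1]]
    b <- profiles[[2]]
    ifelse(a == b, a, "H")
  }
  obs |>
    group_by(.data$event_id, .data$product_id) |>
    summarise(genotype = list(combine(.data$profile)), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "product_id", values_from = "genotype",
      names_glue = "genotype_{tolower(sub('P_', '', product_id))}"
    )
}

#' Generate random sample barcodes
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt.
#' @param min_dist Minimum pairwise Hamming distance.
#' @return A tibble with `recombinant_id` and `barcode`.
#' @export
random_barcodes <- function(n, length = 16, min_dist = 5) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(bases, length, replace = TRUE), collapse = "")
    if (all(vapply(out, function(b) hamming(b, cand) >= min_dist, logical(1)))) {
      out <- c(out, cand)
    }
  }
  tibble(recombinant_id = sprintf("rec%03d", seq_len(n)), barcode = out)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Universal product-specific primer pairs
#'
#' The forward/reverse priming sequences that identify which product an
#' amplicon derives from.
#'
#' @return A tibble with `product_id`, `fwd`, `rev`.
#' @export
universal_primers <- function() {
  tibble(
    product_id = c("P_TRUNC", "P_FULL"),
    fwd = c("ACGAGCTCGAATTCATCGATGATA", "CTTTTTACGCCCACAACAAGAACC"),
    rev = c("TCACTTTTGCCCTGGAACTTAGTG", "GCTTGGGAGTTGGGAATTGAAGTT")
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Realize the full amplicon core sequence of one species from its marker
# allele vector: recipient backbone, donor bases substituted at D markers,
# donor insertion included when the marker nearest the insertion point is
# donor-derived.
species_sequence <- function(profile, pair, map) {
  m <- as_tibble(map)
  chars <- strsplit(pair$recipient_seq, "")[[1]]
  d_idx <- which(profile == "D")
  chars[m$pos_recipient[d_idx] + 1] <- m$donor_base[d_idx]
  ins <- pair$insertion
  if (!is.null(ins)) {
    nearest <- which.min(abs(m$pos_recipient - ins$pos_recipient))
    if (profile[nearest] == "D") {
      chars <- append(chars, strsplit(ins$seq, "")[[1]], after = ins$pos_recipient)
    }
  }
  paste(chars, collapse = "")
}

#' Emit barcoded amplicon reads for observed colony species
#'
#' Reconstructs each species' amplicon sequence from its marker vector and
#' the reference pair, attaches the recombinant barcode and product-specific
#' universal primers, applies uniform substitution errors, and returns
#' flat-quality FASTQ-style records. Ground truth is encoded in read names.
#'
#' @param obs Output of [observe_colony()].
#' @param pair The `allele_pair` the events were simulated on.
#' @param map The `marker_map`.
#' @param barcode_table Tibble mapping `recombinant_id` to `barcode`; events
#'   are assigned barcodes in order of `event_id`.
#' @param depth Reads per species.
#' @param error_rate Per-base substitution error probability.
#' @param primers Universal primer table (default [universal_primers()]).
#' @return A tibble with `read_id`, `sequence`, `quality`.
#' @export
emit_reads <- function(obs, pair, map, barcode_table, depth = 20,
                       error_rate = 0, primers = universal_primers()) {
  stopifnot(depth >= 1)
  ids <- sort(unique(obs$event_id))
  if (length(ids) > nrow(barcode_table)) {
    stop("barcode table has fewer barcodes than events", call. = FALSE)
  }
  bc_of <- setNames(barcode_table$barcode[seq_along(ids)], ids)
  rec_of <- setNames(barcode_table$recombinant_id[seq_along(ids)], ids)
  prim <- setNames(
    lapply(seq_len(nrow(primers)), function(i) primers[i, ]),
    primers$product_id
  )
  rows <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    o <- obs[i, ]
    core <- species_sequence(o$profile[[1]], pair, map)
    pp <- prim[[o$product_id]]
    bc <- bc_of[[as.character(o$event_id)]]
    full <- paste0(bc, pp$fwd, core, revcomp(pp$rev), revcomp(bc))
    seqs <- replicate(depth, add_substitution_errors(full, error_rate))
    flip <- runif(depth) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    rows[[i]] <- tibble(
      read_id = sprintf(
        "%s|%s|sp%d|r%02d", rec_of[[as.character(o$event_id)]],
        o$product_id, o$species, seq_len(depth)
      ),
      sequence = seqs,
      quality = strrep("I", nchar(seqs))
    )
  }
  list_rbind(rows)
}

add_substitution_errors <- function(seq, error_rate) {
  if (error_rate <= 0) {
    return(seq)
  }
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < error_rate)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(bases, b), 1), character(1))
  }
  paste(chars, collapse = "")
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(
    paste0("@", reads$read_id), reads$sequence, "+", reads$quality
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' Qualities are parsed but unused downstream: consensus reads are treated as
#' flat-quality.
#'
#' @param path FASTQ file (plain text).
#' @return Tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4 == 0)
  idx <- seq(1, length(lines), by = 4)
  tibble(
    read_id = sub("^@", "", lines[idx]),
    sequence = lines[idx + 1],
    quality = lines[idx + 3]
  )
}

# ---------------------------------------------------------------------------
# Fluctuation assay simulation
# ---------------------------------------------------------------------------

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Mutations arise during exponential growth: the number of mutations per
#' culture is Poisson with mean `rate * n_cells`, and each mutation founds a
#' clone whose final size follows the classical reciprocal-uniform law
#' (P(size >= s) = 1/s), capped at the culture size. This reproduces the
#' heavy-tailed jackpot behaviour of mutant counts.
#'
#' @param rate Mutation (event) rate per cell per generation.
#' @param n_cells Final viable cells per culture.
#' @param n_cultures Number of parallel cultures.
#' @param seed Optional integer seed.
#' @return A tibble of class `fluctuation_experiment` with columns `culture`
#'   and `mutant_count`, carrying `n_total_cells` as an attribute.
#' @export
simulate_fluctuation <- function(rate, n_cells, n_cultures, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- rate * n_cells
  if (m > 1e4) stop("rate * n_cells too large for tractable simulation", call. = FALSE)
  counts <- vapply(seq_len(n_cultures), function(i) {
    k <- rpois(1, m)
    if (k == 0) {
      return(0)
    }
    sum(pmin(floor(1 / runif(k)), n_cells))
  }, numeric(1))
  structure(
    tibble(culture = seq_len(n_cultures), mutant_count = counts),
    n_total_cells = n_cells,
    class = c("fluctuation_experiment", class(tibble()))
  )
}
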