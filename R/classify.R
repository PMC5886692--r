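# Mechanistic classification of crossover events and initiation inference.

# Recipient-context asymmetric hetDNA positions per side of the anchor,
# over both products. Returns list(up = logical, dn = logical, by_product).
recipient_het_sides <- function(tracts, pos, anchor) {
  het <- tracts |>
    filter(.data$kind %in% c("HETDNA", "SYMMETRIC_HETDNA"))
  rec_het <- het |> filter(.data$context == "RECIPIENT_DERIVED", .data$kind == "HETDNA")
  list(
    up = any(rec_het$side == "UPSTREAM" | rec_het$side == "SPANNING"),
    dn = any(rec_het$side == "DOWNSTREAM" | rec_het$side == "SPANNING"),
    rec_het = rec_het, het = het
  )
}

# bp interval (midpoint convention) of a tract row
tract_edges <- function(tr, pos, span) {
  left <- ifelse(tr$first_marker == 1, span[1],
    (pos[pmax(tr$first_marker - 1, 1)] + pos[tr$first_marker]) / 2
  )
  right <- ifelse(tr$last_marker == length(pos), span[2],
    (pos[tr$last_marker] + pos[pmin(tr$last_marker + 1, length(pos))]) / 2
  )
  cbind(left, right)
}

#' Extract complexity features of a crossover event
#'
#' Measures, relative to the anchor: gap expansion per side (break-adjacent
#' conversion covering one marker = `SINGLE_SNP`, two or more contiguous
#' break-adjacent markers = `MULTI_SNP`), interruption counts (restoration
#' patches and interior conversion patches inside hetDNA), symmetric hetDNA
#' regions tagged `TERMINAL` (at the break-distal end of an asymmetric
#' tract) or `INTERSTITIAL`, donor alterations (hetDNA/conversion tracts in
#' donor-derived context), the sides carrying recipient-context hetDNA, and
#' whether the inter-product hetDNA transition is displaced from the anchor.
#'
#' @inheritParams event_tracts
#' @param tracts Optional precomputed [event_tracts()] table (avoids
#'   recomputation when the caller already has it).
#' @return A one-row tibble of feature columns (`gap_expansion_up`,
#'   `gap_expansion_dn`, `n_restoration_patches`, `n_conversion_patches`,
#'   `n_terminal_symmetric`, `n_interstitial_symmetric`,
#'   `n_donor_alterations`, `hetdna_up`, `hetdna_dn`,
#'   `transition_displaced`, `displacement_bp`).
#' @export
extract_features <- function(genotype_trunc, genotype_full, map, anchor,
                             tracts = NULL) {
  m <- as_tibble(map)
  pos <- m$pos_recipient
  span <- map_span(map)
  tr <- tracts %||% event_tracts(genotype_trunc, genotype_full, map, anchor)

  # gap expansion: conversion run adjacent to the break, per side. The run
  # must include the break-flanking marker on that side.
  gap_side <- function(side) {
    fm <- if (side == "UPSTREAM") max(which(pos < anchor)) else min(which(pos >= anchor))
    conv <- tr |>
      filter(
        .data$kind == "CONVERSION", .data$context == "RECIPIENT_DERIVED",
        .data$first_marker <= fm, .data$last_marker >= fm
      )
    if (nrow(conv) == 0) {
      return("NONE")
    }
    if (max(conv$last_marker - conv$first_marker) + 1 >= 2) "MULTI_SNP" else "SINGLE_SNP"
  }
  gap_up <- if (any(pos < anchor)) gap_side("UPSTREAM") else "NONE"
  gap_dn <- if (any(pos >= anchor)) gap_side("DOWNSTREAM") else "NONE"

  sym <- tr |> filter(.data$kind == "SYMMETRIC_HETDNA")
  terminal <- 0L
  interstitial <- 0L
  if (nrow(sym) > 0) {
    # a symmetric region is terminal when it closes the break-distal end of
    # the partner product's (longer) asymmetric tract: the distal edges of
    # the two products' heteroduplex regions coincide there
    sym_u <- sym |> distinct(.data$first_marker, .data$last_marker, .keep_all = TRUE)
    for (i in seq_len(nrow(sym_u))) {
      s <- sym_u[i, ]
      other <- if (s$product_id == "P_TRUNC") genotype_full else genotype_trunc
      o_h <- which(other == "H")
      is_term <- if (pos[s$first_marker] >= anchor) {
        max(o_h) == s$last_marker # downstream block: distal = right edge
      } else {
        min(o_h) == s$first_marker # upstream block: distal = left edge
      }
      if (is_term) terminal <- terminal + 1L else interstitial <- interstitial + 1L
    }
  }

  donor_alt <- tr |> filter(.data$context == "DONOR_DERIVED", .data$kind != "RESTORATION_PATCH")

  sides <- recipient_het_sides(tr, pos, anchor)
  disp <- transition_displacement(tr, pos, span, anchor)

  tibble(
    gap_expansion_up = gap_up, gap_expansion_dn = gap_dn,
    n_restoration_patches = sum(tr$kind == "RESTORATION_PATCH"),
    n_conversion_patches = sum(
      tr$kind == "CONVERSION" & tr$context == "RECIPIENT_DERIVED" &
        interior_patch(tr)
    ),
    n_terminal_symmetric = terminal,
    n_interstitial_symmetric = interstitial,
    n_donor_alterations = nrow(donor_alt),
    hetdna_up = sides$up, hetdna_dn = sides$dn,
    transition_displaced = disp$displaced,
    displacement_bp = disp$displacement
  )
}

# conversion tracts sandwiched between hetDNA tracts of the same product
interior_patch <- function(tr) {
  vapply(seq_len(nrow(tr)), function(i) {
    if (tr$kind[i] != "CONVERSION") {
      return(FALSE)
    }
    same <- tr[tr$product_id == tr$product_id[i], ]
    any(same$kind %in% c("HETDNA", "SYMMETRIC_HETDNA") &
      same$last_marker == tr$first_marker[i] - 1) &&
      any(same$kind %in% c("HETDNA", "SYMMETRIC_HETDNA") &
        same$first_marker == tr$last_marker[i] + 1)
  }, logical(1))
}

# Inter-product transition between the two recipient-context hetDNA tracts:
# defined when each product carries exactly one, the tracts do not overlap,
# and they are adjacent (separated by at most the inter-marker gap).
# Displacement is measured as transition midpoint minus anchor; it counts as
# displaced when at least one marker lies strictly between anchor and
# transition.
transition_displacement <- function(tr, pos, span, anchor) {
  none <- list(displaced = FALSE, displacement = NA_real_, transition = NA_real_)
  rec_het <- tr |> filter(.data$kind == "HETDNA", .data$context == "RECIPIENT_DERIVED")
  a <- rec_het |> filter(.data$product_id == "P_TRUNC")
  b <- rec_het |> filter(.data$product_id == "P_FULL")
  if (nrow(a) != 1 || nrow(b) != 1) {
    return(none)
  }
  if (a$first_marker > b$first_marker) {
    tmp <- a
    a <- b
    b <- tmp
  }
  if (a$last_marker >= b$first_marker) {
    return(none) # overlapping: symmetric-like, no clean transition
  }
  if (b$first_marker - a$last_marker > 1) {
    return(none) # separated by markers: not an adjacent transition
  }
  transition <- (pos[a$last_marker] + pos[b$first_marker]) / 2
  n_between <- sum(pos > min(anchor, transition) & pos < max(anchor, transition))
  list(
    displaced = n_between >= 1,
    displacement = transition - anchor,
    transition = transition
  )
}

EVENT_CLASSES <- c(
  "TWO_SIDED", "ONE_SIDED_LEFT", "ONE_SIDED_RIGHT", "DISPLACED_TRANSITION",
  "DONOR_ONLY", "CONVERSION_ONLY", "NICK_LIKE", "GAP_LIKE", "UNINTERPRETABLE"
)

#' Classify an induced crossover event against a known break
#'
#' Decision order: (1) no hetDNA anywhere gives `CONVERSION_ONLY`; (2)
#' hetDNA exclusively in donor-derived context gives `DONOR_ONLY`; (3)
#' asymmetric recipient-context hetDNA on both sides of the break in
#' opposite products, with the inter-product transition at the break, gives
#' `TWO_SIDED`; (4) an adjacent inter-product transition displaced from the
#' break gives `DISPLACED_TRANSITION`; (5) hetDNA on exactly one side gives
#' `ONE_SIDED_LEFT`/`ONE_SIDED_RIGHT`; (6) anything else is
#' `UNINTERPRETABLE`.
#'
#' @inheritParams event_tracts
#' @param break_site A `break_site` or numeric anchor.
#' @return One-row tibble: `klass` plus the feature columns of
#'   [extract_features()].
#' @export
classify_induced <- function(genotype_trunc, genotype_full, map, break_site) {
  bs <- as_break_anchor(break_site)
  anchor <- bs$cut_center
  pos <- map_positions(map)
  span <- map_span(map)
  tr <- event_tracts(genotype_trunc, genotype_full, map, anchor)
  feats <- extract_features(genotype_trunc, genotype_full, map, anchor, tracts = tr)

  any_h <- any(genotype_trunc == "H") || any(genotype_full == "H")
  sides <- recipient_het_sides(tr, pos, anchor)
  disp <- transition_displacement(tr, pos, span, anchor)

  klass <- if (!any_h) {
    "CONVERSION_ONLY"
  } else if (nrow(sides$rec_het) == 0 && !any(tr$kind == "SYMMETRIC_HETDNA" & tr$context == "RECIPIENT_DERIVED")) {
    "DONOR_ONLY"
  } else if (isTRUE(disp$displaced)) {
    "DISPLACED_TRANSITION"
  } else if (two_sided_opposite(sides$rec_het)) {
    "TWO_SIDED"
  } else if (sides$up && !sides$dn) {
    "ONE_SIDED_LEFT"
  } else if (sides$dn && !sides$up) {
    "ONE_SIDED_RIGHT"
  } else {
    "UNINTERPRETABLE"
  }
  bind_cols(tibble(klass = klass), feats)
}

# asymmetric hetDNA on both sides of the break, in different products: there
# must be a product with an upstream tract and a *different* product with a
# downstream tract
two_sided_opposite <- function(rec_het) {
  up_products <- unique(rec_het$product_id[rec_het$side %in% c("UPSTREAM", "SPANNING")])
  dn_products <- unique(rec_het$product_id[rec_het$side %in% c("DOWNSTREAM", "SPANNING")])
  length(up_products) > 0 && length(dn_products) > 0 &&
    length(union(up_products, dn_products)) > 1
}

#' Infer the initiating lesion of a spontaneous crossover event
#'
#' With no known break, the event's hetDNA pattern is matched against the
#' predictions of the initiation models: a DSB pattern is asymmetric hetDNA
#' in both products with an inter-product transition (the inferred break sits
#' at the transition midpoint, or at the center of an interstitial conversion
#' tract separating the two tracts); a nick pattern is a single asymmetric
#' tract adjacent to the crossover point in one product only, in
#' donor-derived context; a gap pattern is a symmetric tract at the
#' crossover point with an asymmetric extension in exactly one product. The
#' broken allele of a DSB pattern is the minor-contribution parent (the
#' parental identity replaced by hetDNA).
#'
#' @inheritParams event_tracts
#' @return One-row tibble: `klass`, `lesion_type`, `inferred_allele`,
#'   `inferred_position`, `in_3prime_half`, `anchor` (the crossover point
#'   used for tract accounting).
#' @export
infer_initiation <- function(genotype_trunc, genotype_full, map) {
  m <- as_tibble(map)
  pos <- m$pos_recipient
  span <- map_span(map)
  mid <- (span[1] + span[2]) / 2
  interval_at <- function(p) {
    # local inter-marker interval around position p
    i <- findInterval(p, pos)
    lo <- if (i >= 1) pos[i] else span[1]
    hi <- if (i < length(pos)) pos[i + 1] else span[2]
    hi - lo
  }
  out <- function(klass, lesion = "INDETERMINATE", allele = "INDETERMINATE",
                  position = NA_real_, anchor = NA_real_) {
    tibble(
      klass = klass, lesion_type = lesion, inferred_allele = allele,
      inferred_position = position,
      in_3prime_half = if (is.na(position)) NA else position > mid,
      anchor = anchor
    )
  }

  any_h <- any(genotype_trunc == "H") || any(genotype_full == "H")
  if (!any_h) {
    return(out("CONVERSION_ONLY"))
  }

  segs_t <- segment_product(genotype_trunc, map)
  segs_f <- segment_product(genotype_full, map)
  het_t <- segs_t |> filter(.data$state == "H")
  het_f <- segs_f |> filter(.data$state == "H")

  h_markers_t <- unlist(purrr::map2(het_t$first_marker, het_t$last_marker, seq))
  h_markers_f <- unlist(purrr::map2(het_f$first_marker, het_f$last_marker, seq))
  sym_markers <- intersect(h_markers_t, h_markers_f)

  # ----- DSB pattern: asymmetric hetDNA spans in both products with a
  # transition between them (possibly separated by a conversion tract)
  if (nrow(het_t) > 0 && nrow(het_f) > 0 && length(sym_markers) == 0) {
    span_t <- c(min(het_t$first_marker), max(het_t$last_marker))
    span_f <- c(min(het_f$first_marker), max(het_f$last_marker))
    if (span_t[2] < span_f[1] || span_f[2] < span_t[1]) {
      first <- if (span_t[2] < span_f[1]) span_t else span_f
      second <- if (span_t[2] < span_f[1]) span_f else span_t
      gap_markers <- seq(first[2] + 1, second[1] - 1, length.out = max(0, second[1] - 1 - first[2]))
      position <- (pos[first[2]] + pos[second[1]]) / 2
      # interstitial conversion between the tracts relocates the estimate to
      # the conversion tract's center
      if (length(gap_markers) > 0) {
        gt_gap <- genotype_trunc[gap_markers]
        gf_gap <- genotype_full[gap_markers]
        conv_gap <- gt_gap == "D" | gf_gap == "D" | gt_gap == "R" | gf_gap == "R"
        if (all(gt_gap != "H" & gf_gap != "H") && any(conv_gap)) {
          position <- mean(range(pos[gap_markers[conv_gap]]))
        }
      }
      # broken allele: the minor-contribution parent across both products
      n_r <- sum(genotype_trunc == "R") + sum(genotype_full == "R")
      n_d <- sum(genotype_trunc == "D") + sum(genotype_full == "D")
      allele <- if (n_r < n_d) "RECIPIENT_D5" else if (n_d < n_r) "DONOR_D3" else "INDETERMINATE"
      return(out("TWO_SIDED",
        lesion = "DSB", allele = allele,
        position = position, anchor = position
      ))
    }
  }

  # ----- GAP pattern: symmetric block plus an asymmetric extension in
  # exactly one product
  if (length(sym_markers) > 0) {
    asym_t <- setdiff(h_markers_t, sym_markers)
    asym_f <- setdiff(h_markers_f, sym_markers)
    sym_lo <- min(sym_markers)
    sym_hi <- max(sym_markers)
    contiguous <- identical(sort(sym_markers), seq(sym_lo, sym_hi))
    one_ext <- xor(length(asym_t) > 0, length(asym_f) > 0)
    ext <- if (length(asym_t) > 0) asym_t else asym_f
    adjacent <- length(ext) == 0 ||
      any(ext == sym_lo - 1) || any(ext == sym_hi + 1)
    if (contiguous && one_ext && adjacent) {
      position <- mean(range(pos[sym_markers]))
      return(out("GAP_LIKE",
        lesion = "GAP", allele = "INDETERMINATE",
        position = position, anchor = position
      ))
    }
    return(out("UNINTERPRETABLE", anchor = mean(range(pos[sym_markers]))))
  }

  # ----- NICK pattern: a single tract region in one product only, adjacent
  # to the crossover point, in donor-derived context
  single_t <- nrow(het_t) > 0 && nrow(het_f) == 0
  single_f <- nrow(het_f) > 0 && nrow(het_t) == 0
  if (single_t || single_f) {
    het <- if (single_t) het_t else het_f
    carrier_geno <- if (single_t) genotype_trunc else genotype_full
    other_geno <- if (single_t) genotype_full else genotype_trunc
    carrier_id <- if (single_t) "P_TRUNC" else "P_FULL"
    h_lo <- min(het$first_marker)
    h_hi <- max(het$last_marker)
    # crossover point from the hetDNA-free product: its parental transition
    oi <- which(other_geno != "N" & other_geno != "H")
    change <- which(other_geno[oi][-1] != other_geno[oi][-length(oi)])
    if (length(change) == 1) {
      co_point <- (pos[oi[change]] + pos[oi[change + 1]]) / 2
      # tract must touch the crossover point within one inter-marker interval
      edge_lo <- pos[h_lo]
      edge_hi <- pos[h_hi]
      tol <- interval_at(co_point) + 1e-9
      touches <- (edge_lo - co_point) <= tol && (co_point - edge_hi) <= tol
      # donor-derived context: the tract lies on the side of the carrier's
      # own transition where its flank is donor
      flanks <- product_flanks(if (single_t) segs_t else segs_f, carrier_id)
      tract_side_state <- if (edge_lo >= co_point) flanks[["right"]] else flanks[["left"]]
      if (touches && tract_side_state == "D") {
        return(out("NICK_LIKE",
          lesion = "NICK", allele = "INDETERMINATE",
          position = co_point, anchor = co_point
        ))
      }
    }
    return(out("UNINTERPRETABLE"))
  }

  out("UNINTERPRETABLE")
}

#' Classify a table of events
#'
#' Applies [classify_induced()] (when a break site is supplied) or
#' [infer_initiation()] (spontaneous mode) to every event and binds the
#' results to the event table. In spontaneous mode, events with an inferred
#' crossover point also get the feature columns computed at that anchor.
#'
#' @param events Tibble with `event_id`, `genotype_trunc`, `genotype_full`.
#' @param map A `marker_map`.
#' @param break_site A `break_site`/numeric anchor for induced events, or
#'   `NULL` for spontaneous inference.
#' @return The events tibble with `klass` and feature/inference columns.
#' @export
classify_events <- function(events, map, break_site = NULL) {
  res <- purrr::map(seq_len(nrow(events)), function(i) {
    gt <- events$genotype_trunc[[i]]
    gf <- events$genotype_full[[i]]
    if (!is.null(break_site)) {
      classify_induced(gt, gf, map, break_site)
    } else {
      infer_initiation(gt, gf, map)
    }
  }) |> list_rbind()
  bind_cols(select(events, -dplyr::any_of(names(res))), res)
}
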