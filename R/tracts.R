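# Tract segmentation and hetDNA length measurement.

#' Segment a product genotype vector into maximal runs
#'
#' Collapses a per-marker genotype vector over `{R, D, H, N}` into maximal
#' same-state segments. `N` markers are absorbed into a flanking run when the
#' nearest informative neighbours on both sides share a state; otherwise they
#' are excluded from every segment and reported in the `excluded` attribute.
#'
#' @param genotype Character vector of per-marker calls.
#' @param map A `marker_map` (positions give each segment its bp span).
#' @return A tibble with columns `state`, `first_marker`, `last_marker`
#'   (ordinal marker indices, inclusive), `bp_start`, `bp_end` (half-open
#'   recipient-frame span of the member markers), `n_markers`; attribute
#'   `excluded` lists unassignable `N` marker indices.
#' @export
segment_product <- function(genotype, map) {
  m <- as_tibble(map)
  stopifnot(length(genotype) == nrow(m))
  info <- which(genotype != "N")
  if (length(info) == 0) stop("all-N genotype vector cannot be segmented", call. = FALSE)

  eff <- genotype
  excluded <- integer(0)
  for (i in which(genotype == "N")) {
    left <- info[info < i]
    right <- info[info > i]
    if (length(left) > 0 && length(right) > 0 &&
      genotype[max(left)] == genotype[min(right)]) {
      eff[i] <- genotype[max(left)]
    } else {
      eff[i] <- NA_character_
      excluded <- c(excluded, i)
    }
  }
  keep <- which(!is.na(eff))
  states <- eff[keep]
  # runs break where the state changes; excluded markers are simply skipped,
  # matching a linear scan over the informative markers
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  first_marker <- keep[starts]
  last_marker <- keep[ends]
  out <- tibble(
    state = r$values,
    first_marker = first_marker,
    last_marker = last_marker,
    bp_start = m$pos_recipient[first_marker],
    bp_end = m$pos_recipient[last_marker] + 1,
    n_markers = r$lengths
  )
  attr(out, "excluded") <- excluded
  out
}

# Parental flank identities of a product. These are fixed by the amplicon
# structure, not inferred from the observed calls: the doubly-truncated
# product inherits the recipient arm upstream and the donor arm downstream
# of the crossover, and the full-length product the reverse. (Observed
# outermost segments can be misleading: a tract may run to the homology
# border, or mismatch repair may convert an outermost marker.)
product_flanks <- function(segments, product_id) {
  if (identical(product_id, "P_FULL")) {
    c(left = "D", right = "R")
  } else {
    c(left = "R", right = "D")
  }
}

# Parental context allele at each marker position for one product: the
# origin of the flank on that side of the anchor.
context_alleles <- function(pos, anchor, flanks) {
  ifelse(pos < anchor, flanks[["left"]], flanks[["right"]])
}

#' Extract hetDNA, conversion and restoration tracts from an event
#'
#' Classifies every non-parental segment of both products relative to the
#' anchor (the known break for induced events, the inferred crossover point
#' for spontaneous ones): `H` segments become `HETDNA` tracts (relabelled
#' `SYMMETRIC_HETDNA` when both products carry `H` at identical marker
#' positions); `D` segments in recipient-derived context become
#' `CONVERSION`; `R` segments in donor-derived context become `CONVERSION`
#' with donor context (donor alterations); parental-state segments flanked on
#' both sides by hetDNA become `RESTORATION_PATCH`.
#'
#' Tract lengths use inter-marker midpoints: a tract extends from the
#' midpoint between its outermost member marker and the nearest marker
#' beyond it (or to the homology border when none exists).
#'
#' @param genotype_trunc,genotype_full Per-marker genotype vectors of the two
#'   products.
#' @param map A `marker_map`.
#' @param anchor Recipient-frame bp position of the initiating lesion.
#' @return Tibble with one row per tract: `product_id`, `kind`, `side`,
#'   `context`, `first_marker`, `last_marker`, `length_bp`.
#' @export
event_tracts <- function(genotype_trunc, genotype_full, map, anchor) {
  span <- map_span(map)
  if (anchor < span[1] || anchor >= span[2]) {
    stop("anchor outside homology span", call. = FALSE)
  }
  m <- as_tibble(map)
  pos <- m$pos_recipient

  per_product <- function(genotype, product_id) {
    segs <- segment_product(genotype, map)
    # split non-hetDNA segments that straddle the anchor, so each piece has a
    # uniform parental context (a conversion run can merge with the opposite
    # flank otherwise); hetDNA segments keep their SPANNING identity
    straddle <- which(
      segs$state != "H" &
        pos[segs$first_marker] < anchor & pos[segs$last_marker] >= anchor
    )
    if (length(straddle) > 0) {
      extra <- list()
      for (k in straddle) {
        fmk <- segs$first_marker[k]
        lmk <- segs$last_marker[k]
        cutk <- max(which(pos[fmk:lmk] < anchor)) + fmk - 1L
        extra[[length(extra) + 1]] <- mutate(segs[k, ],
          first_marker = cutk + 1L, bp_start = pos[cutk + 1L],
          n_markers = lmk - cutk
        )
        segs$last_marker[k] <- cutk
        segs$bp_end[k] <- pos[cutk] + 1
        segs$n_markers[k] <- cutk - fmk + 1L
      }
      segs <- arrange(bind_rows(segs, list_rbind(extra)), .data$first_marker)
    }
    flanks <- product_flanks(segs, product_id)
    ctx <- context_alleles(pos, anchor, flanks)
    n_seg <- nrow(segs)
    st <- segs$state
    fm <- segs$first_marker
    lm <- segs$last_marker
    ctx_l <- ctx[fm]
    ctx_r <- ctx[lm]
    interior <- seq_len(n_seg) > 1 & seq_len(n_seg) < n_seg &
      c("", st[-n_seg]) == "H" & c(st[-1], "") == "H"

    kind <- rep(NA_character_, n_seg)
    context <- rep(NA_character_, n_seg)
    is_h <- st == "H"
    kind[is_h] <- "HETDNA"
    context[is_h] <- ifelse(ctx_l[is_h] == "R" | ctx_r[is_h] == "R",
      "RECIPIENT_DERIVED", "DONOR_DERIVED"
    )
    nonpar <- !is_h & st != ctx_l & st != ctx_r
    kind[nonpar] <- "CONVERSION"
    context[nonpar] <- ifelse(ctx_l[nonpar] == "R", "RECIPIENT_DERIVED", "DONOR_DERIVED")
    patch <- !is_h & !nonpar & interior
    kind[patch] <- "RESTORATION_PATCH"
    context[patch] <- ifelse(st[patch] == "R", "RECIPIENT_DERIVED", "DONOR_DERIVED")

    sel <- !is.na(kind)
    if (!any(sel)) {
      return(NULL)
    }
    tibble(
      product_id = product_id, kind = kind[sel],
      side = ifelse(pos[lm[sel]] < anchor, "UPSTREAM",
        ifelse(pos[fm[sel]] >= anchor, "DOWNSTREAM", "SPANNING")
      ),
      context = context[sel],
      first_marker = fm[sel], last_marker = lm[sel]
    )
  }

  empty <- tibble(
    product_id = character(), kind = character(), side = character(),
    context = character(), first_marker = integer(), last_marker = integer()
  )
  tr <- bind_rows(
    empty,
    per_product(genotype_trunc, "P_TRUNC"),
    per_product(genotype_full, "P_FULL")
  )
  if (nrow(tr) == 0) {
    return(mutate(tr, length_bp = numeric(0)))
  }

  # symmetric hetDNA: an H segment whose markers are all heteroduplex in the
  # other product as well (hetDNA present in both duplexes at the same
  # positions; the symmetric block may be nested inside a longer asymmetric
  # tract of the partner, as after junction migration)
  for (r in which(tr$kind == "HETDNA")) {
    other <- if (tr$product_id[r] == "P_TRUNC") genotype_full else genotype_trunc
    members <- tr$first_marker[r]:tr$last_marker[r]
    if (all(other[members] == "H")) tr$kind[r] <- "SYMMETRIC_HETDNA"
  }

  tr |>
    mutate(
      length_bp = tract_length(.data$first_marker, .data$last_marker, pos, span)
    )
}

# Midpoint-extended bp length of a marker run.
tract_length <- function(first_marker, last_marker, pos, span) {
  left <- ifelse(first_marker == 1, span[1],
    (pos[pmax(first_marker - 1, 1)] + pos[first_marker]) / 2
  )
  right <- ifelse(last_marker == length(pos), span[2],
    (pos[last_marker] + pos[pmin(last_marker + 1, length(pos))]) / 2
  )
  right - left
}

# Non-parental marker indicator per product: H anywhere, or a parental-state
# call that differs from the product's context allele at that position.
nonparental_markers <- function(genotype, map, anchor, product_id) {
  pos <- map_positions(map)
  segs <- segment_product(genotype, map)
  flanks <- product_flanks(segs, product_id)
  ctx <- context_alleles(pos, anchor, flanks)
  genotype != "N" & (genotype == "H" | genotype != ctx)
}

#' hetDNA length on one side of the anchor
#'
#' Distance from the anchor to the most break-distal transition from
#' heteroduplex to homoduplex DNA (or between donor and recipient sequence)
#' on the given side, over both products. The transition point is the
#' midpoint between the outermost non-parental marker (hetDNA, or
#' conversion in either direction) and the next marker beyond it; when the
#' outermost such marker is the last before the homology border, the length
#' extends to the border. Returns 0 when the side carries no hetDNA or
#' conversion.
#'
#' @inheritParams event_tracts
#' @param side `"UPSTREAM"` or `"DOWNSTREAM"`.
#' @return Length in bp.
#' @export
hetdna_length <- function(genotype_trunc, genotype_full, map, side, anchor) {
  side <- match.arg(side, c("UPSTREAM", "DOWNSTREAM"))
  pos <- map_positions(map)
  span <- map_span(map)
  on_side <- if (side == "UPSTREAM") pos < anchor else pos >= anchor
  if (!any(on_side)) stop("no markers on side ", side, call. = FALSE)

  np <- nonparental_markers(genotype_trunc, map, anchor, "P_TRUNC") |
    nonparental_markers(genotype_full, map, anchor, "P_FULL")
  idx <- which(np & on_side)
  if (length(idx) == 0) {
    return(0)
  }
  if (side == "UPSTREAM") {
    outer <- min(idx)
    transition <- if (outer == 1) span[1] else (pos[outer - 1] + pos[outer]) / 2
    anchor - transition
  } else {
    outer <- max(idx)
    transition <- if (outer == length(pos)) span[2] else (pos[outer] + pos[outer + 1]) / 2
    transition - anchor
  }
}

#' Total hetDNA length of an event
#'
#' Span between the two most break-distal transitions: the sum of the
#' upstream and downstream lengths when both sides carry hetDNA/conversion,
#' or the single side's length otherwise. Errors when the event carries
#' none.
#'
#' @inheritParams hetdna_length
#' @return Length in bp.
#' @export
total_hetdna_length <- function(genotype_trunc, genotype_full, map, anchor) {
  up <- hetdna_length(genotype_trunc, genotype_full, map, "UPSTREAM", anchor)
  dn <- hetdna_length(genotype_trunc, genotype_full, map, "DOWNSTREAM", anchor)
  if (up == 0 && dn == 0) {
    stop("event carries no hetDNA or conversion; total length undefined", call. = FALSE)
  }
  up + dn
}

#' Per-event hetDNA length table
#'
#' @param events Tibble with `event_id`, `genotype_trunc`, `genotype_full`
#'   list-columns (e.g. from [sim_genotypes()] or [call_events()]), and
#'   optionally an `anchor` column.
#' @param map A `marker_map`.
#' @param anchor Anchor position(s); a single value, a vector (one per
#'   event), or `NULL` to use the events' `anchor` column.
#' @param het_only Restrict the tract definition to true hetDNA (`H`)
#'   markers when computing presence; lengths still use the most distal
#'   non-parental transition. Events without any `H` marker get
#'   `has_hetdna = FALSE`.
#' @return Tibble with `event_id`, `upstream_bp`, `downstream_bp`,
#'   `total_bp`, `has_hetdna`.
#' @export
hetdna_length_table <- function(events, map, anchor = NULL, het_only = TRUE) {
  anchors <- if (is.null(anchor)) events$anchor else rep_len(anchor, nrow(events))
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    gt <- events$genotype_trunc[[i]]
    gf <- events$genotype_full[[i]]
    a <- anchors[i]
    has_h <- any(gt == "H") || any(gf == "H")
    up <- hetdna_length(gt, gf, map, "UPSTREAM", a)
    dn <- hetdna_length(gt, gf, map, "DOWNSTREAM", a)
    tibble(
      event_id = events$event_id[i],
      upstream_bp = up, downstream_bp = dn,
      total_bp = if (up == 0 && dn == 0) NA_real_ else up + dn,
      has_hetdna = has_h
    )
  })
  list_rbind(rows)
}
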