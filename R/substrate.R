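# Substrate model: allele pair, break site, marker map.

#' Construct an allele pair from two substrate sequences
#'
#' Globally aligns the recipient (broken) and donor (repair template)
#' homology regions and validates that they differ only by isolated
#' substitutions plus at most one short donor insertion (the inactivated cut
#' site). The alignment defines the recipient-frame coordinate system used by
#' every downstream stage.
#'
#' @param recipient_seq,donor_seq Uppercase ACGT character strings.
#' @param min_identity Reject pairs whose global alignment identity falls
#'   below this fraction (default 0.90); a lower identity signals wrong
#'   inputs rather than engineered SNPs.
#' @return An object of class `allele_pair`: a list with the two sequences,
#'   their homology spans (half-open, 0-based), the substitution table, and
#'   the donor insertion (position + sequence) if present.
#' @export
allele_pair <- function(recipient_seq, donor_seq, min_identity = 0.90) {
  recipient_seq <- toupper(recipient_seq)
  donor_seq <- toupper(donor_seq)
  for (s in list(recipient = recipient_seq, donor = donor_seq)) {
    if (grepl("[^ACGT]", s)) {
      stop("substrate sequences must contain only A/C/G/T", call. = FALSE)
    }
  }
  # fixed scoring: substitutions must stay cheaper than gap pairs so that
  # engineered SNPs are never represented as indels; the single short donor
  # insertion is still affordable against the alternative of a frame shift
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(recipient_seq), Biostrings::DNAString(donor_seq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2),
    gapOpening = 12, gapExtension = 3
  )
  aln_r <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  aln_d <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  n_match <- sum(aln_r == aln_d & aln_r != "-")
  identity <- n_match / length(aln_r)
  if (identity < min_identity) {
    stop(sprintf(
      "alignment identity %.3f below %.2f: are these the right substrates?",
      identity, min_identity
    ), call. = FALSE)
  }

  pos_r <- cumsum(aln_r != "-") - 1L  # 0-based recipient offset per column
  pos_d <- cumsum(aln_d != "-") - 1L

  sub_cols <- which(aln_r != "-" & aln_d != "-" & aln_r != aln_d)
  substitutions <- tibble(
    pos_recipient = pos_r[sub_cols],
    pos_donor = pos_d[sub_cols],
    recipient_base = aln_r[sub_cols],
    donor_base = aln_d[sub_cols]
  )

  # Donor-only insertions appear as gap runs in the recipient row.
  ins_cols <- which(aln_r == "-")
  insertion <- NULL
  if (length(ins_cols) > 0) {
    runs <- split(ins_cols, cumsum(c(1L, diff(ins_cols) != 1L)))
    if (length(runs) > 1) {
      stop("more than one donor insertion found; substrate pair unusable",
        call. = FALSE
      )
    }
    run <- runs[[1]]
    insertion <- list(
      # recipient position the insertion sits in front of
      pos_recipient = pos_r[run[1]] + 1L,
      length = length(run),
      seq = paste(aln_d[run], collapse = "")
    )
  }
  del_cols <- which(aln_d == "-")
  if (length(del_cols) > 0) {
    stop("donor has a deletion relative to the recipient; unsupported pair",
      call. = FALSE
    )
  }

  structure(
    list(
      recipient_seq = recipient_seq,
      donor_seq = donor_seq,
      homology_span_recipient = c(0L, nchar(recipient_seq)),
      homology_span_donor = c(0L, nchar(donor_seq)),
      substitutions = substitutions,
      insertion = insertion,
      identity = identity
    ),
    class = "allele_pair"
  )
}

#' @export
print.allele_pair <- function(x, ...) {
  cat(sprintf(
    "<allele_pair> %d bp recipient / %d bp donor, %d substitutions, %s, identity %.3f\n",
    nchar(x$recipient_seq), nchar(x$donor_seq), nrow(x$substitutions),
    if (is.null(x$insertion)) "no insertion" else {
      sprintf("%d-bp donor insertion at %d", x$insertion$length, x$insertion$pos_recipient)
    },
    x$identity
  ))
  invisible(x)
}

#' Load an allele pair from two single-record FASTA files
#'
#' @param recipient_fasta,donor_fasta Paths to FASTA files holding exactly
#'   one record each.
#' @param ... Passed to [allele_pair()].
#' @return An `allele_pair`.
#' @export
load_allele_pair <- function(recipient_fasta, donor_fasta, ...) {
  read_one <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1) {
      stop(sprintf("%s holds %d records; expected exactly 1", path, length(set)),
        call. = FALSE
      )
    }
    as.character(set[[1]])
  }
  allele_pair(read_one(recipient_fasta), read_one(donor_fasta), ...)
}

#' Locate the nuclease break site in the recipient substrate
#'
#' Finds the recognition motif (default: the 18-bp I-SceI site) in the
#' recipient homology region and returns the two nick positions producing the
#' 4-nt 3' overhang, plus the cut center used as the anchor for all
#' upstream/downstream logic. The motif must be absent (inactivated) in the
#' donor.
#'
#' @param pair An `allele_pair`.
#' @param recognition_motif Recognition sequence; must occur exactly once in
#'   the recipient.
#' @param nick_offsets Integer offsets of the two strand nicks from the motif
#'   start (0-based; the overhang is the interval between them).
#' @return An object of class `break_site`: list with `cut_center`,
#'   `three_prime_end_left`, `three_prime_end_right`,
#'   `recognition_site_span`.
#' @export
locate_break <- function(pair, recognition_motif = ISCEI_MOTIF,
                         nick_offsets = ISCEI_NICKS) {
  stopifnot(inherits(pair, "allele_pair"))
  hits <- gregexpr(recognition_motif, pair$recipient_seq, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) == 0) stop("recognition motif absent from recipient", call. = FALSE)
  if (length(hits) > 1) stop("recognition motif occurs more than once in recipient", call. = FALSE)
  if (grepl(recognition_motif, pair$donor_seq, fixed = TRUE)) {
    stop("recognition motif is intact (cleavable) in the donor; donor site must be inactivated",
      call. = FALSE
    )
  }
  s <- hits[1] - 1L # 0-based motif start
  left <- s + nick_offsets[[1]]
  right <- s + nick_offsets[[2]]
  stopifnot(left < right)
  structure(
    list(
      cut_center = (left + right) / 2,
      three_prime_end_left = left,
      three_prime_end_right = right,
      recognition_site_span = c(s, s + nchar(recognition_motif))
    ),
    class = "break_site"
  )
}

#' @export
print.break_site <- function(x, ...) {
  cat(sprintf(
    "<break_site> cut center %.1f, 3' ends %d/%d, site [%d, %d)\n",
    x$cut_center, x$three_prime_end_left, x$three_prime_end_right,
    x$recognition_site_span[1], x$recognition_site_span[2]
  ))
  invisible(x)
}

#' Derive the SNP marker map from an allele pair
#'
#' Every aligned substitution becomes a marker with its side relative to the
#' break and its distance to the nearer 3' end of the cut. The donor-only
#' insertion is a product-identity feature, not a genotyping marker: it is
#' recorded as an attribute and excluded from the marker rows.
#'
#' @param pair An `allele_pair`.
#' @param break_site A `break_site` from [locate_break()], or a bare numeric
#'   anchor position (both 3' ends taken equal to it).
#' @return A tibble of class `marker_map` with columns `index`,
#'   `pos_recipient`, `pos_donor`, `recipient_base`, `donor_base`, `side`,
#'   `dist_to_break`, carrying the break site and insertion as attributes.
#' @export
derive_marker_map <- function(pair, break_site) {
  stopifnot(inherits(pair, "allele_pair"))
  bs <- as_break_anchor(break_site)
  subs <- pair$substitutions
  if (nrow(subs) == 0) {
    stop("no markers: the two substrates carry no substitutions", call. = FALSE)
  }
  span <- pair$homology_span_recipient
  if (bs$cut_center < span[1] || bs$cut_center >= span[2]) {
    stop("break lies outside the homology span", call. = FALSE)
  }
  m <- subs |>
    arrange(.data$pos_recipient) |>
    mutate(
      index = row_number(),
      side = if_else(.data$pos_recipient < bs$cut_center, "UPSTREAM", "DOWNSTREAM"),
      dist_to_break = pmin(
        abs(.data$pos_recipient - bs$three_prime_end_left),
        abs(.data$pos_recipient - bs$three_prime_end_right)
      )
    ) |>
    select(
      "index", "pos_recipient", "pos_donor", "recipient_base",
      "donor_base", "side", "dist_to_break"
    )
  if (anyDuplicated(m$pos_recipient) > 0) {
    stop("two markers share a recipient position", call. = FALSE)
  }
  new_marker_map(m,
    break_site = bs, insertion = pair$insertion,
    homology_span = span
  )
}

new_marker_map <- function(df, break_site, insertion, homology_span) {
  structure(
    as_tibble(df),
    break_site = break_site,
    insertion = insertion,
    homology_span = homology_span,
    class = c("marker_map", class(as_tibble(df)))
  )
}

as_break_anchor <- function(break_site) {
  if (inherits(break_site, "break_site")) {
    return(break_site)
  }
  if (is.numeric(break_site) && length(break_site) == 1) {
    return(structure(
      list(
        cut_center = break_site,
        three_prime_end_left = break_site,
        three_prime_end_right = break_site,
        recognition_site_span = c(break_site, break_site)
      ),
      class = "break_site"
    ))
  }
  stop("break_site must be a <break_site> or a single numeric position",
    call. = FALSE
  )
}

#' Map a recipient-frame position to the donor frame
#'
#' Accounts for the donor-only insertion: positions at or beyond it shift by
#' the insertion length. Monotone non-decreasing in its argument.
#'
#' @param pair An `allele_pair`.
#' @param pos_recipient Numeric vector of 0-based recipient positions.
#' @return Donor-frame positions.
#' @export
map_donor_coordinate <- function(pair, pos_recipient) {
  span <- pair$homology_span_recipient
  if (any(pos_recipient < span[1] | pos_recipient >= span[2])) {
    stop("position outside recipient homology span", call. = FALSE)
  }
  if (is.null(pair$insertion)) {
    return(pos_recipient)
  }
  pos_recipient + ifelse(pos_recipient >= pair$insertion$pos_recipient,
    pair$insertion$length, 0L
  )
}

#' Map a donor-frame position back to the recipient frame
#'
#' Inverse of [map_donor_coordinate()] for positions outside the insertion;
#' positions inside the donor insertion collapse onto the insertion point.
#'
#' @param pair An `allele_pair`.
#' @param pos_donor Numeric vector of 0-based donor positions.
#' @return Recipient-frame positions.
#' @export
map_recipient_coordinate <- function(pair, pos_donor) {
  span <- pair$homology_span_donor
  if (any(pos_donor < span[1] | pos_donor >= span[2])) {
    stop("position outside donor homology span", call. = FALSE)
  }
  if (is.null(pair$insertion)) {
    return(pos_donor)
  }
  ins <- pair$insertion
  ifelse(pos_donor < ins$pos_recipient, pos_donor,
    ifelse(pos_donor < ins$pos_recipient + ins$length,
      ins$pos_recipient,
      pos_donor - ins$length
    )
  )
}

#' Write a marker map to TSV
#'
#' @param map A `marker_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

#' Write a break site to JSON
#'
#' @param break_site A `break_site`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_break_site <- function(break_site, path) {
  jsonlite::write_json(unclass(break_site), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic substrate pair
#'
#' Builds a recipient/donor allele pair emulating the engineered assay
#' design: a shared homology region carrying silent SNP markers at roughly
#' even spacing, a single nuclease recognition site in the recipient, a
#' flanking marker 8 bp from each 3' end of the cut, and the donor site
#' inactivated by a 6-bp insertion. The sequences are synthetic stand-ins for
#' the real substrates (which are not distributed with the package); every
#' structural property used by the analysis is reproduced.
#'
#' Defaults follow the assay's stated design: 4100 bp of homology, 82
#' markers at ~50-bp intervals, and the cut site placed so that ~2 kb of
#' homology lies upstream of it.
#'
#' @param homology_len Homology length in bp.
#' @param n_markers Total marker count (including the two break-flanking
#'   markers).
#' @param site_start 0-based start of the recognition motif in the recipient.
#' @param seed Integer seed controlling the backbone sequence and SNP base
#'   choices (the layout itself is deterministic).
#' @return A list with `recipient_seq`, `donor_seq`, `marker_pos`
#'   (true recipient-frame marker positions), `site_start`,
#'   `insertion_pos` (recipient-frame point in front of which the donor
#'   insertion sits).
#' @export
synthetic_substrates <- function(homology_len = 4100, n_markers = 82,
                                 site_start = 2000, seed = 42) {
  stopifnot(n_markers >= 2, homology_len > site_start + 60)
  motif <- ISCEI_MOTIF
  s <- as.integer(site_start)
  tpl <- s + ISCEI_NICKS[["left"]]
  tpr <- s + ISCEI_NICKS[["right"]]
  flank_up <- tpl - 8L
  flank_dn <- tpr + 8L

  # Remaining markers split between the sides proportionally to available
  # room, at ~even spacing outside a guard window around the site.
  n_rest <- n_markers - 2L
  up_room <- flank_up - 30L
  dn_room <- (homology_len - 30L) - flank_dn
  n_up <- round(n_rest * up_room / (up_room + dn_room))
  n_dn <- n_rest - n_up
  pos_up <- if (n_up > 0) round(seq(30, flank_up - 40, length.out = n_up)) else integer()
  pos_dn <- if (n_dn > 0) round(seq(flank_dn + 40, homology_len - 30, length.out = n_dn)) else integer()
  marker_pos <- sort(unique(c(pos_up, flank_up, flank_dn, pos_dn)))
  stopifnot(length(marker_pos) == n_markers)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  repeat {
    backbone <- sample(bases, homology_len, replace = TRUE)
    backbone[(s + 1):(s + nchar(motif))] <- strsplit(motif, "")[[1]]
    recipient <- paste(backbone, collapse = "")
    # motif must be unique in the recipient and the donor must not contain an
    # intact copy once the insertion is added (checked below)
    if (length(gregexpr(motif, recipient, fixed = TRUE)[[1]]) == 1 &&
      gregexpr(motif, recipient, fixed = TRUE)[[1]][1] == s + 1) {
      break
    }
  }

  donor <- backbone
  for (p in marker_pos) {
    donor[p + 1] <- sample(setdiff(bases, backbone[p + 1]), 1)
  }
  ins_pos <- tpr # insertion directly after the nick-flanked overhang region
  donor_seq <- paste(
    c(donor[seq_len(ins_pos)], strsplit(DONOR_SITE_INSERTION, "")[[1]], donor[(ins_pos + 1):homology_len]),
    collapse = ""
  )
  if (grepl(motif, donor_seq, fixed = TRUE)) {
    stop("internal: donor unexpectedly retains an intact recognition site")
  }
  list(
    recipient_seq = recipient,
    donor_seq = donor_seq,
    marker_pos = marker_pos,
    site_start = s,
    insertion_pos = ins_pos
  )
}

#' Build the synthetic substrate pair, break site and marker map in one call
#'
#' Convenience wrapper chaining [synthetic_substrates()], [allele_pair()],
#' [locate_break()] and [derive_marker_map()].
#'
#' @inheritParams synthetic_substrates
#' @return List with `pair`, `break_site`, `map`, and the raw `truth` layout.
#' @export
synthetic_assay <- function(homology_len = 4100, n_markers = 82,
                            site_start = 2000, seed = 42) {
  truth <- synthetic_substrates(homology_len, n_markers, site_start, seed)
  pair <- allele_pair(truth$recipient_seq, truth$donor_seq)
  bs <- locate_break(pair)
  map <- derive_marker_map(pair, bs)
  list(pair = pair, break_site = bs, map = map, truth = truth)
}
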