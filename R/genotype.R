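# Demultiplexing, per-read marker profiling, species clustering, QC and
# product genotype calls.

# Hamming distances between the leading `len` characters of each sequence
# and each reference: returns a length(seqs) x length(refs) matrix.
prefix_dist <- function(seqs, refs) {
  len <- nchar(refs[1])
  pre <- substr(seqs, 1, len)
  chars <- matrix(unlist(strsplit(sprintf("%-*s", len, pre), "")),
    nrow = length(seqs), byrow = TRUE
  )
  out <- matrix(0L, nrow = length(seqs), ncol = length(refs))
  for (j in seq_along(refs)) {
    rc <- strsplit(refs[j], "")[[1]]
    out[, j] <- rowSums(chars != matrix(rc, nrow = length(seqs), ncol = len, byrow = TRUE))
  }
  out
}

validate_barcode_table <- function(barcode_table, min_dist = 5) {
  bc <- barcode_table$barcode
  if (anyDuplicated(bc)) stop("duplicate barcode sequences", call. = FALSE)
  if (length(bc) > 1) {
    for (i in seq_len(length(bc) - 1)) {
      for (j in seq(i + 1, length(bc))) {
        if (hamming(bc[i], bc[j]) < min_dist) {
          stop(sprintf(
            "barcodes %s and %s closer than Hamming %d",
            barcode_table$recombinant_id[i], barcode_table$recombinant_id[j], min_dist
          ), call. = FALSE)
        }
      }
    }
  }
  invisible(barcode_table)
}

#' Demultiplex barcoded amplicon reads
#'
#' Assigns each read to the unique barcode within Hamming distance
#' `max_mismatch` of its leading barcode-length window (both orientations
#' tried) and to a product by its universal forward-primer flank.
#' Unassignable reads are routed to the `"unassigned"` status with a reason,
#' never dropped.
#'
#' @param reads Tibble with `read_id`, `sequence` (e.g. from
#'   [read_fastq()]).
#' @param barcode_table Tibble with `recombinant_id`, `barcode`; barcodes
#'   must be pairwise Hamming distance >= 5 apart.
#' @param primers Universal primer table (default [universal_primers()]).
#' @param max_mismatch Maximum barcode mismatches (default 2).
#' @param primer_max_mismatch Maximum forward-primer mismatches (default 5).
#' @return Tibble with `read_id`, `recombinant_id`, `product_id`, `core`
#'   (the read trimmed of barcode/primer flanks, reference orientation),
#'   `status` (`"assigned"`/`"unassigned"`), `reason`.
#' @export
demultiplex <- function(reads, barcode_table, primers = universal_primers(),
                        max_mismatch = 2, primer_max_mismatch = 5) {
  validate_barcode_table(barcode_table)
  bc_len <- nchar(barcode_table$barcode[1])
  n <- nrow(reads)
  seq_fwd <- reads$sequence
  seq_rev <- revcomp(seq_fwd)
  d_fwd <- prefix_dist(seq_fwd, barcode_table$barcode)
  d_rev <- prefix_dist(seq_rev, barcode_table$barcode)

  recombinant_id <- rep(NA_character_, n)
  product_id <- rep(NA_character_, n)
  core <- rep(NA_character_, n)
  status <- rep("unassigned", n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    done <- FALSE
    for (orient in c("fwd", "rev")) {
      d <- if (orient == "fwd") d_fwd[i, ] else d_rev[i, ]
      hit <- which(d <= max_mismatch)
      if (length(hit) == 0) next
      s <- if (orient == "fwd") seq_fwd[i] else seq_rev[i]
      if (length(hit) > 1) {
        reason[i] <- "ambiguous barcode"
        done <- TRUE
        break
      }
      # both amplicon ends carry the barcode, so the flanking primer — a
      # forward primer in reference orientation, a reverse primer otherwise —
      # decides both the product and the reading direction
      flank <- substr(s, bc_len + 1, nchar(s))
      pd <- c(
        prefix_dist(flank, primers$fwd)[1, ],
        prefix_dist(flank, primers$rev)[1, ]
      )
      phit <- which(pd <= primer_max_mismatch)
      if (length(phit) != 1) {
        reason[i] <- if (length(phit) == 0) "no primer match" else "ambiguous primer"
        done <- TRUE
        break
      }
      np <- nrow(primers)
      j <- ((phit - 1) %% np) + 1
      is_fwd <- phit <= np
      status[i] <- "assigned"
      recombinant_id[i] <- barcode_table$recombinant_id[hit]
      product_id[i] <- primers$product_id[j]
      mid <- if (is_fwd) {
        substr(
          s, bc_len + nchar(primers$fwd[j]) + 1,
          nchar(s) - bc_len - nchar(primers$rev[j])
        )
      } else {
        revcomp(substr(
          s, bc_len + nchar(primers$rev[j]) + 1,
          nchar(s) - bc_len - nchar(primers$fwd[j])
        ))
      }
      core[i] <- mid
      done <- TRUE
      break
    }
    if (!done) reason[i] <- "no barcode within distance"
  }
  tibble(
    read_id = reads$read_id, recombinant_id = recombinant_id,
    product_id = product_id, core = core, status = status, reason = reason
  )
}

#' Call marker profiles for a set of reads
#'
#' Globally aligns each read core to both parental references; the
#' higher-scoring alignment frames the marker columns. Each marker is called
#' `R` when the read base matches the recipient allele, `D` for the donor
#' allele, and `N` otherwise (including a deletion at the column). Reads
#' whose best alignment identity falls below `min_identity` get an all-`N`
#' profile and a QC flag.
#'
#' @param cores Character vector of trimmed read sequences (reference
#'   orientation).
#' @param pair An `allele_pair`.
#' @param map A `marker_map`.
#' @param min_identity Minimum acceptable alignment identity (default 0.80).
#' @return A list of per-read profile character vectors; attribute
#'   `low_identity` flags failed reads.
#' @export
call_read_profiles <- function(cores, pair, map, min_identity = 0.80) {
  m <- as_tibble(map)
  n_mark <- nrow(m)
  pats <- Biostrings::DNAStringSet(cores)
  pa_r <- Biostrings::pairwiseAlignment(
    pats, Biostrings::DNAString(pair$recipient_seq),
    type = "global"
  )
  pa_d <- Biostrings::pairwiseAlignment(
    pats, Biostrings::DNAString(pair$donor_seq),
    type = "global"
  )
  use_d <- Biostrings::score(pa_d) > Biostrings::score(pa_r)

  # aligned() projects each read onto subject coordinates (insertions
  # dropped, deletions gapped), so marker columns are direct lookups
  mat_r <- as.matrix(Biostrings::aligned(pa_r))[, m$pos_recipient + 1, drop = FALSE]
  mat_d <- as.matrix(Biostrings::aligned(pa_d))[, m$pos_donor + 1, drop = FALSE]
  ident <- ifelse(use_d, Biostrings::pid(pa_d), Biostrings::pid(pa_r)) / 100

  low <- ident < min_identity
  profiles <- vector("list", length(cores))
  for (i in seq_along(cores)) {
    if (low[i]) {
      profiles[[i]] <- rep("N", n_mark)
      next
    }
    base <- if (use_d[i]) mat_d[i, ] else mat_r[i, ]
    out <- rep("N", n_mark)
    out[base == m$recipient_base] <- "R"
    out[base == m$donor_base] <- "D"
    profiles[[i]] <- out
  }
  attr(profiles, "low_identity") <- low
  profiles
}

#' @rdname call_read_profiles
#' @param core A single read core sequence.
#' @return For `call_read_profile`: one profile character vector.
#' @export
call_read_profile <- function(core, pair, map, min_identity = 0.80) {
  call_read_profiles(core, pair, map, min_identity)[[1]]
}

#' Cluster read profiles into consensus species
#'
#' Profiles are grouped by exact equality on their non-`N` calls: an `N`
#' matches anything and the profile merges into the compatible group with
#' the largest support (ties resolved toward the earlier-created group).
#' The cluster consensus fills `N` positions from its members.
#'
#' @param profiles List of per-marker profile vectors.
#' @param min_reads Minimum profile count to attempt clustering (default 3).
#' @return Tibble of class `species_table`: `species`, `profile` (list),
#'   `support`, `fraction`, sorted by support descending.
#' @export
cluster_species <- function(profiles, min_reads = 3) {
  if (length(profiles) == 0) stop("no profiles to cluster", call. = FALSE)
  if (length(profiles) < min_reads) {
    warning("fewer than ", min_reads, " profiles; clustering anyway")
  }
  key <- vapply(profiles, paste, character(1), collapse = "")
  groups <- tibble(key = key) |>
    count(.data$key, name = "support") |>
    arrange(desc(.data$support))
  groups$profile <- strsplit(groups$key, "")

  clusters <- list() # each: list(consensus, support)
  compatible <- function(a, b) all(a == b | a == "N" | b == "N")
  for (g in seq_len(nrow(groups))) {
    prof <- groups$profile[[g]]
    comp <- which(vapply(clusters, function(cl) compatible(cl$consensus, prof), logical(1)))
    if (length(comp) == 0) {
      clusters[[length(clusters) + 1]] <- list(consensus = prof, support = groups$support[g])
    } else {
      sup <- vapply(clusters[comp], function(cl) cl$support, numeric(1))
      tgt <- comp[which.max(sup)] # which.max takes the first on ties
      cl <- clusters[[tgt]]
      cons <- cl$consensus
      fill <- cons == "N" & prof != "N"
      cons[fill] <- prof[fill]
      clusters[[tgt]] <- list(consensus = cons, support = cl$support + groups$support[g])
    }
  }
  out <- tibble(
    profile = purrr::map(clusters, "consensus"),
    support = vapply(clusters, function(cl) cl$support, numeric(1))
  ) |>
    arrange(desc(.data$support)) |>
    mutate(species = row_number(), fraction = .data$support / sum(.data$support)) |>
    select("species", "profile", "support", "fraction")
  structure(out, class = c("species_table", class(out)))
}

major_species <- function(species, min_support = 2, major_fraction = 0.10) {
  filter(species, .data$support >= min_support, .data$fraction >= major_fraction)
}

#' QC verdict for one recombinant's clustered products
#'
#' A species is "major" when it has at least `min_support` reads and at
#' least `major_fraction` of the product's reads. A recombinant with more
#' than two major species in either product is regarded as spurious.
#'
#' @param species_trunc,species_full `species_table`s of the two products.
#' @param min_support,major_fraction Major-species thresholds.
#' @return One-row tibble: `qc_pass`, `n_major_trunc`, `n_major_full`.
#' @export
qc_event <- function(species_trunc, species_full, min_support = 2,
                     major_fraction = 0.10) {
  n_t <- nrow(major_species(species_trunc, min_support, major_fraction))
  n_f <- nrow(major_species(species_full, min_support, major_fraction))
  tibble(
    qc_pass = n_t <= 2 && n_f <= 2,
    n_major_trunc = n_t, n_major_full = n_f
  )
}

#' Product genotype from clustered species
#'
#' With a single major species the genotype is its profile. With two, the
#' per-marker rule is: equal calls pass through; an `R`-vs-`D` disagreement
#' is diagnostic of heteroduplex DNA and becomes `H`; any call versus `N`
#' yields the non-`N` call. Minor species are ignored.
#'
#' @param species A `species_table`.
#' @param min_support,major_fraction Major-species thresholds.
#' @return List with `genotype` (character vector over markers in
#'   `{R, D, H, N}`) and `n_major_species`.
#' @export
product_genotype <- function(species, min_support = 2, major_fraction = 0.10) {
  maj <- major_species(species, min_support, major_fraction)
  if (nrow(maj) == 0) stop("no major species for product", call. = FALSE)
  if (nrow(maj) == 1) {
    return(list(genotype = maj$profile[[1]], n_major_species = 1L))
  }
  a <- maj$profile[[1]]
  b <- maj$profile[[2]]
  genotype <- dplyr::case_when(
    a == b ~ a,
    a == "N" ~ b,
    b == "N" ~ a,
    .default = "H"
  )
  list(genotype = genotype, n_major_species = nrow(maj))
}

#' Call per-event product genotypes from reads
#'
#' Full read-level pipeline: demultiplex, per-read marker profiling,
#' species clustering, QC, and hetDNA-diagnosing genotype combination, per
#' recombinant.
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param barcode_table Tibble with `recombinant_id`, `barcode`.
#' @param pair An `allele_pair`.
#' @param map A `marker_map`.
#' @param min_reads Minimum reads per product (QC fail below).
#' @param min_support,major_fraction Major-species thresholds.
#' @param min_identity Per-read alignment identity threshold.
#' @return Tibble with one row per recombinant: `event_id`
#'   (recombinant_id), `genotype_trunc`, `genotype_full` (list-columns),
#'   `qc_pass`, `n_major_trunc`, `n_major_full`, `n_reads`; attribute
#'   `unassigned` holds the unassigned read table.
#' @export
call_events <- function(reads, barcode_table, pair, map, min_reads = 3,
                        min_support = 2, major_fraction = 0.10,
                        min_identity = 0.80) {
  dmx <- demultiplex(reads, barcode_table)
  asg <- filter(dmx, .data$status == "assigned")
  profiles <- call_read_profiles(asg$core, pair, map, min_identity)
  asg$profile <- profiles

  n_mark <- nrow(as_tibble(map))
  rows <- list()
  for (rec in unique(asg$recombinant_id)) {
    sub <- filter(asg, .data$recombinant_id == rec)
    per_product <- list()
    qc_ok <- TRUE
    n_major <- c(P_TRUNC = 0L, P_FULL = 0L)
    for (product in c("P_TRUNC", "P_FULL")) {
      pr <- filter(sub, .data$product_id == product)$profile
      if (length(pr) < min_reads) {
        qc_ok <- FALSE
        per_product[[product]] <- rep("N", n_mark)
        next
      }
      sp <- cluster_species(pr, min_reads)
      n_major[[product]] <- nrow(major_species(sp, min_support, major_fraction))
      if (n_major[[product]] == 0 || n_major[[product]] > 2) {
        qc_ok <- FALSE
        per_product[[product]] <- rep("N", n_mark)
        next
      }
      per_product[[product]] <- product_genotype(sp, min_support, major_fraction)$genotype
    }
    rows[[length(rows) + 1]] <- tibble(
      event_id = rec,
      genotype_trunc = list(per_product$P_TRUNC),
      genotype_full = list(per_product$P_FULL),
      qc_pass = qc_ok,
      n_major_trunc = n_major[["P_TRUNC"]],
      n_major_full = n_major[["P_FULL"]],
      n_reads = nrow(sub)
    )
  }
  out <- list_rbind(rows) |> arrange(.data$event_id)
  attr(out, "unassigned") <- filter(dmx, .data$status == "unassigned")
  out
}
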