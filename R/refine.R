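#' Annotate SV type and length on raw VCF rows
#'
#' Resolves the SV type of each raw row in priority order: the INFO `SVTYPE`
#' key when recognised, then a symbolic ALT token (`<DEL>`, `<DUP:TANDEM>`,
#' ...), then sequence-resolved REF/ALT length difference (net gain = INS,
#' net loss = DEL). Breakend (BND) records are classified from the junction
#' orientation encoded in the ALT allele: for a same-contig mate pair at
#' positions p1 < p2, `t[p2[` at p1 is a deletion junction, `]p2]t` at p1 a
#' tandem-duplication junction, and matching-side orientations (`t]p2]` or
#' `[p2[t`) an inversion; a mate on another contig is a translocation (CTX).
#'
#' Lengths are `|SVLEN|` when present, else `END - POS` for DEL/DUP/INV
#' (mate distance for breakends), else the REF/ALT length difference;
#' translocations and symbolic insertions without `SVLEN` have no length.
#' Unclassifiable rows are dropped with a warning; the count of dropped rows
#' is attached as attribute `n_dropped`.
#'
#' @param raw Tibble of raw rows from [read_caller_vcf()].
#' @return An annotated SV tibble (one row per classified call, input order
#'   preserved) with columns `contig`, `pos`, `end`, `svtype`, `svlen`,
#'   `filter`, `caller`, `record_id`, `mate_id`, `mate_contig`, `extra_info`.
#' @export
annotate_sv <- function(raw) {
  if (!is.data.frame(raw)) abort("`raw` must be a data frame of raw VCF rows.")
  if (nrow(raw) == 0) {
    out <- empty_sv_tbl()
    attr(out, "contig_order") <- attr(raw, "contig_order")
    return(set_count_attr(out, "n_dropped", 0))
  }

  alt_index <- raw$alt_index %||% rep(1L, nrow(raw))
  info <- raw$info %||% rep(NA_character_, nrow(raw))
  info_svtype <- info_value(info, "SVTYPE")
  info_svlen <- suppressWarnings(as.integer(info_element(info_value(info, "SVLEN"), alt_index)))
  info_end <- suppressWarnings(as.integer(info_element(info_value(info, "END"), alt_index)))
  mate_id <- info_value(info, "MATEID")
  event <- info_value(info, "EVENT")

  # Breakend ALT: optional bases, bracket, mate locus, bracket, optional bases.
  bnd <- stringr::str_match(
    raw$alt, "^([A-Za-z.*]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([A-Za-z.*]*)$"
  )
  is_bnd_alt <- !is.na(bnd[, 1])
  symbolic <- stringr::str_match(raw$alt, "^<([A-Za-z]+)(?::[^>]*)?>$")[, 2]

  known <- c(SV_TYPES, "BND", "TRA")
  svtype <- ifelse(!is.na(info_svtype) & info_svtype %in% known, info_svtype, NA)
  svtype <- ifelse(is.na(svtype) & !is.na(symbolic) & symbolic %in% known, symbolic, svtype)
  svtype[is.na(svtype) & is_bnd_alt] <- "BND"
  svtype[svtype == "TRA"] <- "CTX"

  # Sequence-resolved alleles: classify by net length change.
  seqres <- is.na(svtype) & !is.na(raw$alt) &
    stringr::str_detect(raw$alt, "^[ACGTNacgtn]+$") &
    stringr::str_detect(raw$ref, "^[ACGTNacgtn]+$")
  diff <- nchar(raw$alt) - nchar(raw$ref)
  svtype[seqres & diff > 0] <- "INS"
  svtype[seqres & diff < 0] <- "DEL"

  # Resolve breakends via the mate locus in the ALT string.
  mate_contig <- rep(NA_character_, nrow(raw))
  mate_pos <- rep(NA_integer_, nrow(raw))
  resolve <- !is.na(svtype) & svtype == "BND"
  if (any(resolve)) {
    mate_contig[resolve] <- bnd[resolve, 4]
    mate_pos[resolve] <- as.integer(bnd[resolve, 5])
    no_mate <- resolve & is.na(mate_contig)
    svtype[no_mate] <- NA  # BND without parseable mate: unclassifiable
    inter <- resolve & !is.na(mate_contig) & mate_contig != raw$contig
    svtype[inter] <- "CTX"
    intra <- resolve & !is.na(mate_contig) & mate_contig == raw$contig
    if (any(intra)) {
      t_before <- nzchar(bnd[intra, 2])  # bases precede the first bracket
      open1 <- bnd[intra, 3]
      matching <- bnd[intra, 3] == bnd[intra, 6] &
        ((t_before & open1 == "]") | (!t_before & open1 == "["))
      lower <- raw$pos[intra] <= mate_pos[intra]
      # At the lower breakend: t[p2[ -> DEL, ]p2]t -> DUP; mirrored at the upper.
      del_like <- t_before & open1 == "[" & bnd[intra, 3] == bnd[intra, 6]
      dup_like <- !t_before & open1 == "]" & bnd[intra, 3] == bnd[intra, 6]
      type <- dplyr::case_when(
        matching ~ "INV",
        (del_like & lower) | (dup_like & !lower) ~ "DEL",
        (dup_like & lower) | (del_like & !lower) ~ "DUP",
        .default = NA_character_
      )
      svtype[intra] <- type
    }
  }

  svlen <- info_svlen
  svlen <- ifelse(is.na(svlen) & !is.na(mate_pos), abs(mate_pos - raw$pos), svlen)
  svlen <- ifelse(
    is.na(svlen) & svtype %in% c("DEL", "DUP", "INV") & !is.na(info_end),
    info_end - raw$pos, svlen
  )
  svlen <- ifelse(is.na(svlen) & seqres, abs(diff), svlen)
  svlen <- abs(as.integer(svlen))
  svlen[!is.na(svtype) & svtype == "CTX"] <- NA_integer_

  end <- info_end
  end <- ifelse(
    is.na(end) & svtype %in% c("DEL", "DUP", "INV") & !is.na(svlen),
    raw$pos + svlen, end
  )
  end[!is.na(mate_pos) & !is.na(svtype) & svtype != "CTX"] <-
    pmax(raw$pos, mate_pos)[!is.na(mate_pos) & !is.na(svtype) & svtype != "CTX"]

  keep <- !is.na(svtype) & svtype %in% SV_TYPES
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warn(paste0("Dropped ", n_dropped, " unclassifiable record(s)."))
  }

  # Pair linkage key for deduplication: MATEID > EVENT > "_1"/"_2" ID stem.
  # Stem keys are provisional; deduplicate_paired() only honors them for an
  # exact complementary same-type pair, so unrelated records whose IDs
  # merely share a prefix are never collapsed.
  stem <- stringr::str_match(raw$record_id, "^(.*)_[12]$")[, 2]
  pair_key <- dplyr::case_when(
    !is.na(mate_id) ~ purrr::map2_chr(raw$record_id, mate_id,
                                      ~ paste(sort(c(.x, .y)), collapse = "|")),
    !is.na(event) ~ paste0("event:", event),
    !is.na(stem) ~ paste0("stem:", stem),
    .default = NA_character_
  )

  out <- tibble::tibble(
    contig = raw$contig,
    pos = as.integer(raw$pos),
    end = as.integer(end),
    svtype = svtype,
    svlen = svlen,
    filter = raw$filter %||% rep("PASS", nrow(raw)),
    caller = raw$caller %||% rep(NA_character_, nrow(raw)),
    record_id = raw$record_id %||% rep(".", nrow(raw)),
    mate_id = mate_id,
    mate_contig = mate_contig,
    pair_key = pair_key,
    extra_info = info
  )[keep, ]

  attr(out, "contig_order") <- attr(raw, "contig_order")
  set_count_attr(out, "n_dropped", n_dropped)
}

#' Exclude SVs below a minimum size
#'
#' Keeps records with `svlen >= min_size`. Records with no defined length
#' (translocations; symbolic insertions lacking `SVLEN`) are kept, since
#' their size is unknowable rather than known-small. The number of removed
#' records is attached as attribute `n_removed`.
#'
#' @param records Annotated SV tibble.
#' @param min_size Minimum SV length in bp (default 50).
#' @return Filtered tibble, input order preserved.
#' @export
filter_min_size <- function(records, min_size = 50) {
  assert_sv_tbl(records)
  if (min_size < 0) abort("`min_size` must be >= 0.")
  keep <- is.na(records$svlen) | records$svlen >= min_size
  out <- records[keep, ]
  attr(out, "contig_order") <- attr(records, "contig_order")
  set_count_attr(out, "n_removed", sum(!keep))
}

#' Collapse paired start/end records of the same SV
#'
#' Some callers report both junction sides of one SV as two linked records
#' (via `MATEID`, a shared `EVENT`, or `_1`/`_2` ID suffixes). For each
#' linked set on one contig, only the record with the smallest position is
#' kept (the end-position record is removed); for inter-contig pairs the
#' record on the later contig in `contig_order` is removed. A mate ID that
#' points to a missing record leaves the survivor in place with a warning.
#' Removed and orphaned counts are attached as attributes `n_removed` and
#' `n_orphaned`.
#'
#' @param records Annotated SV tibble.
#' @param contig_order Optional character vector giving contig precedence;
#'   defaults to the `contig_order` attribute (VCF header order), then
#'   natural sort.
#' @return Deduplicated tibble, input order of survivors preserved.
#' @export
deduplicate_paired <- function(records, contig_order = NULL) {
  assert_sv_tbl(records)
  contig_order <- contig_order %||% attr(records, "contig_order")
  pair_key <- records$pair_key %||% rep(NA_character_, nrow(records))
  has_mate <- !is.na(records$mate_id %||% rep(NA_character_, nrow(records)))

  keep <- rep(TRUE, nrow(records))
  n_orphaned <- 0L
  for (key in unique(pair_key[!is.na(pair_key)])) {
    idx <- which(!is.na(pair_key) & pair_key == key)
    if (length(idx) < 2) {
      if (any(has_mate[idx])) n_orphaned <- n_orphaned + length(idx)
      next
    }
    if (startsWith(key, "stem:")) {
      # ID-stem linkage is honored only for an unambiguous complementary
      # pair describing one SV: two records, suffixes _1 and _2, same type.
      suffixes <- stringr::str_match(records$record_id[idx], "_([12])$")[, 2]
      if (length(idx) != 2 || !setequal(suffixes, c("1", "2")) ||
          length(unique(records$svtype[idx])) != 1) {
        next
      }
    }
    rank <- contig_rank(records$contig[idx], contig_order)
    winner <- idx[order(rank, records$pos[idx])][1]
    keep[setdiff(idx, winner)] <- FALSE
  }
  if (n_orphaned > 0) {
    warn(paste0(n_orphaned, " mate record(s) missing; survivors kept."))
  }
  out <- records[keep, ]
  attr(out, "contig_order") <- attr(records, "contig_order")
  out <- set_count_attr(out, "n_removed", sum(!keep))
  set_count_attr(out, "n_orphaned", n_orphaned)
}

#' Keep only records whose FILTER is exactly PASS
#'
#' A missing FILTER (`"."`) is treated as not PASS and removed. The number
#' of removed records is attached as attribute `n_removed`.
#'
#' @param records Annotated SV tibble.
#' @param pass_only If `FALSE`, records pass through unchanged.
#' @return Filtered tibble.
#' @export
filter_pass <- function(records, pass_only = TRUE) {
  assert_sv_tbl(records)
  if (!pass_only) return(set_count_attr(records, "n_removed", 0))
  filter <- records$filter %||% rep("PASS", nrow(records))
  keep <- !is.na(filter) & filter == "PASS"
  out <- records[keep, ]
  attr(out, "contig_order") <- attr(records, "contig_order")
  set_count_attr(out, "n_removed", sum(!keep))
}

#' Tag records with their caller label
#'
#' Sets the `caller` column on every record (overwriting any existing
#' label); the label is serialized as the INFO key `caller=<NAME>` by
#' [write_sv_vcf()].
#'
#' @param records Annotated SV tibble.
#' @param caller Non-empty caller label.
#' @return The tibble with `caller` set.
#' @export
tag_caller <- function(records, caller) {
  assert_sv_tbl(records)
  if (!is.character(caller) || length(caller) != 1 || is.na(caller) || !nzchar(caller)) {
    abort("`caller` must be a single non-empty string.")
  }
  records$caller <- caller
  records
}

#' Refine a raw caller call set
#'
#' Applies the four refinement steps in order -- type/length annotation,
#' minimum-size exclusion, paired-record deduplication, PASS filtering --
#' then tags every surviving record with the caller label. Per-step removal
#' counts are attached as a `stats` attribute (a tibble with columns `step`,
#' `n_in`, `n_removed`, `n_out`).
#'
#' @param raw Raw rows from [read_caller_vcf()].
#' @param caller Caller label; defaults to the label already on `raw`.
#' @param min_size Minimum SV length in bp (default 50).
#' @param pass_only Keep only FILTER == "PASS" records (default `TRUE`).
#' @param dedup_paired Collapse linked mate records (default `TRUE`).
#' @return Refined, caller-tagged SV tibble.
#' @export
refine_calls <- function(raw, caller = NULL, min_size = 50, pass_only = TRUE,
                         dedup_paired = TRUE) {
  caller <- caller %||% unique(raw$caller %||% NA_character_)[1]
  ann <- annotate_sv(raw)
  sized <- filter_min_size(ann, min_size)
  deduped <- if (dedup_paired) deduplicate_paired(sized) else
    set_count_attr(sized, "n_removed", 0)
  passed <- filter_pass(deduped, pass_only)
  out <- if (!is.na(caller)) tag_caller(passed, caller) else passed

  stats <- tibble::tibble(
    step = c("annotate", "size_filter", "dedup_paired", "pass_filter"),
    n_in = c(nrow(raw), nrow(ann), nrow(sized), nrow(deduped)),
    n_removed = c(
      attr(ann, "n_dropped"), attr(sized, "n_removed"),
      attr(deduped, "n_removed"), attr(passed, "n_removed")
    ),
    n_out = c(nrow(ann), nrow(sized), nrow(deduped), nrow(passed))
  )
  attr(out, "stats") <- stats
  attr(out, "contig_order") <- attr(raw, "contig_order")
  out
}

#' Summarize SV lengths per type
#'
#' Computes count, minimum, median, maximum and interquartile range of
#' `svlen` per SV type. Translocations (no length) are reported as a count
#' only; records with unknown length are counted but excluded from the
#' statistics. Quartiles use R's default convention (type 7); the median of
#' an even-sized set is the mean of the two central values.
#'
#' @param records Annotated SV tibble.
#' @return A tibble with columns `svtype`, `count`, `min`, `median`, `max`,
#'   `iqr`.
#' @export
summarize_lengths <- function(records) {
  assert_sv_tbl(records)
  records |>
    dplyr::group_by(.data$svtype) |>
    dplyr::summarise(
      count = dplyr::n(),
      min = if (all(is.na(.data$svlen))) NA_real_ else min(.data$svlen, na.rm = TRUE),
      median = if (all(is.na(.data$svlen))) NA_real_ else median(.data$svlen, na.rm = TRUE),
      max = if (all(is.na(.data$svlen))) NA_real_ else max(.data$svlen, na.rm = TRUE),
      iqr = if (all(is.na(.data$svlen))) NA_real_ else
        unname(diff(quantile(.data$svlen, c(0.25, 0.75), na.rm = TRUE))),
      .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$svtype, levels = SV_TYPES))
}
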