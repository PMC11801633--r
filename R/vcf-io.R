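#' Read a caller VCF into a tibble of raw variant rows
#'
#' Reads a VCF 4.x file (plain or gzip) and returns one row per (record, ALT
#' allele): multi-allelic records are split, with list-valued `SVLEN`/`END`
#' INFO values taken positionally. Header metadata (contig order, raw meta
#' lines) is attached as attributes so refined records can be written back
#' out with a consistent contig order.
#'
#' @param path Path to a VCF file.
#' @param caller Caller label attached to every row (may be `NA` to tag
#'   later with [tag_caller()]).
#' @return A tibble with columns `contig`, `pos`, `record_id`, `ref`, `alt`,
#'   `alt_index`, `qual`, `filter`, `info`, `caller`, in input order, with
#'   attributes `contig_order` and `meta`.
#' @export
read_caller_vcf <- function(path, caller = NA_character_) {
  if (!file.exists(path)) {
    abort(paste0("VCF file not found: ", path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  meta <- v@meta
  contig_order <- stringr::str_match(meta, "^##contig=<ID=([^,>]+)")[, 2]
  contig_order <- contig_order[!is.na(contig_order)]

  if (nrow(fix) == 0) {
    out <- tibble::tibble(
      contig = character(), pos = integer(), record_id = character(),
      ref = character(), alt = character(), alt_index = integer(),
      qual = character(), filter = character(), info = character(),
      caller = character()
    )
    attr(out, "contig_order") <- contig_order
    attr(out, "meta") <- meta
    return(out)
  }

  raw <- tibble::tibble(
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    record_id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = fix[, "QUAL"],
    filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]),
    info = fix[, "INFO"],
    line = seq_len(nrow(fix))
  )

  # Same non-missing ID reused with conflicting coordinates is a corrupt file.
  ided <- raw[raw$record_id != ".", ]
  if (nrow(ided)) {
    conflicts <- ided |>
      dplyr::distinct(.data$record_id, .data$contig, .data$pos, .keep_all = TRUE) |>
      dplyr::count(.data$record_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conflicts)) {
      bad <- conflicts$record_id[1]
      line <- ided$line[ided$record_id == bad][2]
      abort(paste0(
        "Duplicate record ID '", bad, "' with conflicting coordinates ",
        "(data line ", line, ") in ", path
      ))
    }
  }

  # Split multi-allelic rows one row per ALT; first-ALT precedence is kept by
  # taking SVLEN/END positionally downstream via `alt_index`.
  raw <- raw |>
    dplyr::mutate(alt_split = stringr::str_split(.data$alt, stringr::fixed(","))) |>
    tidyr::unnest_longer("alt_split", indices_to = "alt_index") |>
    dplyr::mutate(alt = .data$alt_split, alt_index = as.integer(.data$alt_index)) |>
    dplyr::select(
      "contig", "pos", "record_id", "ref", "alt", "alt_index",
      "qual", "filter", "info"
    ) |>
    dplyr::mutate(caller = caller)

  attr(raw, "contig_order") <- contig_order
  attr(raw, "meta") <- meta
  raw
}

#' Read a BED file of confident regions
#'
#' BED intervals are 0-based, half-open. Parsing is strict: a malformed line
#' (fewer than three fields, non-integer coordinates, or end <= start) is a
#' hard error naming the line number.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `contig`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  out <- purrr::map(idx, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(paste0("Malformed BED line ", i, ": fewer than 3 fields"))
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start) {
      abort(paste0("Malformed BED line ", i, ": bad interval [",
                   fields[2], ", ", fields[3], ")"))
    }
    tibble::tibble(contig = fields[1], start = start, end = end)
  })
  if (length(out) == 0) {
    return(tibble::tibble(contig = character(), start = integer(), end = integer()))
  }
  dplyr::bind_rows(out)
}

#' Write annotated SV records as a VCF 4.2 file
#'
#' Emits plain-text VCF 4.2 with symbolic ALT alleles and INFO keys
#' `SVTYPE`, `SVLEN`, `END`, plus `caller`, `SUPP` and `GROUP_SIZE` where the
#' corresponding columns are present. Under the `"paired"` dialect, DEL, DUP
#' and INV records are written as two breakend (BND) lines linked by
#' `MATEID`, mimicking callers that report both junction sides;
#' [deduplicate_paired()] reduces them back to one record.
#'
#' @param records Annotated SV tibble (see [annotate_sv()]).
#' @param path Output file path.
#' @param dialect `"plain"` (symbolic ALTs) or `"paired"` (BND mates for
#'   DEL/DUP/INV).
#' @param contigs Optional named vector of contig lengths for the header;
#'   defaults to the records' contigs (or a `contigs` attribute if present).
#' @return Invisibly, `path`.
#' @export
write_sv_vcf <- function(records, path, dialect = c("plain", "paired"),
                         contigs = NULL) {
  dialect <- match.arg(dialect)
  assert_sv_tbl(records)
  contigs <- contigs %||% attr(records, "contigs")
  if (is.null(contigs)) {
    contigs <- setNames(rep(NA_integer_, length(unique(records$contig))),
                        natural_contig_sort(records$contig))
  }

  header <- c(
    "##fileformat=VCFv4.2",
    purrr::imap_chr(as.list(contigs), function(len, nm) {
      if (is.na(len)) paste0("##contig=<ID=", nm, ">")
      else paste0("##contig=<ID=", nm, ",length=", format(len, scientific = FALSE), ">")
    }),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=caller,Number=1,Type=String,Description=\"Detecting caller label(s)\">",
    "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Number of distinct supporting callers\">",
    "##INFO=<ID=GROUP_SIZE,Number=1,Type=Integer,Description=\"Neighbor group member count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )

  body <- if (nrow(records)) format_vcf_body(records, dialect) else character()
  readr::write_lines(c(header, body), path)
  invisible(path)
}

format_vcf_body <- function(records, dialect) {
  n <- nrow(records)
  ids <- records$record_id %||% paste0("sv", seq_len(n))
  ids[is.na(ids) | ids == "."] <- paste0("sv", which(is.na(ids) | ids == "."))
  svlen <- if ("svlen" %in% names(records)) records$svlen else rep(NA_integer_, n)
  end <- if ("end" %in% names(records)) records$end else rep(NA_integer_, n)
  filter <- if ("filter" %in% names(records)) records$filter else rep("PASS", n)
  filter[is.na(filter)] <- "."

  info_extra <- rep("", n)
  add_key <- function(extra, key, value) {
    has <- !is.na(value)
    extra[has] <- paste0(extra[has], ";", key, "=", value[has])
    extra
  }
  if ("caller" %in% names(records)) info_extra <- add_key(info_extra, "caller", records$caller)
  if ("supp" %in% names(records)) info_extra <- add_key(info_extra, "SUPP", records$supp)
  if ("group_size" %in% names(records)) info_extra <- add_key(info_extra, "GROUP_SIZE", records$group_size)

  paired <- dialect == "paired" &
    records$svtype %in% c("DEL", "DUP", "INV") &
    !is.na(svlen)

  lines <- character(0)
  for (i in seq_len(n)) {
    if (paired[i]) {
      p1 <- records$pos[i]
      p2 <- if (!is.na(end[i])) end[i] else p1 + svlen[i]
      ctg <- records$contig[i]
      alts <- switch(records$svtype[i],
        DEL = c(paste0("N[", ctg, ":", p2, "["), paste0("]", ctg, ":", p1, "]N")),
        DUP = c(paste0("]", ctg, ":", p2, "]N"), paste0("N[", ctg, ":", p1, "[")),
        INV = c(paste0("N]", ctg, ":", p2, "]"), paste0("[", ctg, ":", p1, "[N"))
      )
      id1 <- paste0(ids[i], "_1")
      id2 <- paste0(ids[i], "_2")
      lines <- c(lines,
        paste(ctg, p1, id1, "N", alts[1], ".", filter[i],
              paste0("SVTYPE=BND;MATEID=", id2, info_extra[i]), sep = "\t"),
        paste(ctg, p2, id2, "N", alts[2], ".", filter[i],
              paste0("SVTYPE=BND;MATEID=", id1, info_extra[i]), sep = "\t")
      )
    } else {
      info <- paste0("SVTYPE=", records$svtype[i])
      if (!is.na(svlen[i])) info <- paste0(info, ";SVLEN=", svlen[i])
      if (!is.na(end[i])) info <- paste0(info, ";END=", end[i])
      info <- paste0(info, info_extra[i])
      lines <- c(lines,
        paste(records$contig[i], records$pos[i], ids[i], "N",
              paste0("<", records$svtype[i], ">"), ".", filter[i], info,
              sep = "\t")
      )
    }
  }
  lines
}
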