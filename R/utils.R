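#' Round half away from zero
#'
#' `base::round()` rounds half to even; published benchmark tables use the
#' conventional "0.625 -> 0.63" display, so reports round halves up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Extract the value of a single INFO key from raw INFO strings.
# Returns NA where the key is absent; flag keys (no "=") return "TRUE".
info_value <- function(info, key) {
  info <- ifelse(is.na(info), "", info)
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  flag <- is.na(m) & stringr::str_detect(info, paste0("(?:^|;)", key, "(?:;|$)"))
  m[flag] <- "TRUE"
  m
}

# i-th comma-separated element of a possibly list-valued INFO value,
# falling back to the whole value when it is not list-valued.
info_element <- function(value, i) {
  out <- value
  listy <- !is.na(value) & stringr::str_detect(value, stringr::fixed(","))
  if (any(listy)) {
    parts <- stringr::str_split(value[listy], stringr::fixed(","))
    idx <- pmin(i[listy], lengths(parts))
    out[listy] <- purrr::map2_chr(parts, idx, ~ .x[.y])
  }
  out
}

# Natural sort of contig names: "chr2" before "chr10", non-numeric suffixes last.
natural_contig_sort <- function(contigs) {
  contigs <- unique(contigs)
  prefix <- stringr::str_replace(contigs, "([0-9]+)$", "")
  num <- suppressWarnings(as.numeric(stringr::str_match(contigs, "([0-9]+)$")[, 2]))
  contigs[order(prefix, is.na(num), num, contigs)]
}

# Rank contigs by a configured order (e.g. VCF header), appending unseen
# contigs in natural-sort order so every contig gets a finite rank.
contig_rank <- function(contig, contig_order = NULL) {
  order_vec <- c(contig_order, setdiff(natural_contig_sort(contig), contig_order))
  match(contig, order_vec)
}

# Columns every annotated SV tibble carries.
sv_columns <- function() {
  c(
    "contig", "pos", "end", "svtype", "svlen", "filter", "caller",
    "record_id", "mate_id", "mate_contig", "extra_info"
  )
}

empty_sv_tbl <- function() {
  tibble::tibble(
    contig = character(), pos = integer(), end = integer(),
    svtype = character(), svlen = integer(), filter = character(),
    caller = character(), record_id = character(), mate_id = character(),
    mate_contig = character(), extra_info = character()
  )
}

assert_sv_tbl <- function(x, arg = "records") {
  if (!is.data.frame(x)) {
    abort(paste0("`", arg, "` must be a data frame of annotated SV records."))
  }
  missing <- setdiff(c("contig", "pos", "svtype"), names(x))
  if (length(missing)) {
    abort(paste0(
      "`", arg, "` is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Carry an integer count of removed/dropped records on a result.
set_count_attr <- function(x, name, value) {
  attr(x, name) <- as.integer(value)
  x
}
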