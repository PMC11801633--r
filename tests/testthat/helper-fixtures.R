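# Shared fixtures and independent oracles for the test suite.

# Minimal annotated SV tibble.
make_sv <- function(pos, caller = "A", svtype = "DEL", contig = "chr1",
                    svlen = 100L, filter = "PASS", record_id = NULL) {
  n <- length(pos)
  tibble::tibble(
    contig = rep_len(contig, n),
    pos = as.integer(pos),
    end = NA_integer_,
    svtype = rep_len(svtype, n),
    svlen = as.integer(rep_len(svlen, n)),
    filter = rep_len(filter, n),
    caller = rep_len(caller, n),
    record_id = record_id %||% paste0(rep_len(caller, n), "_", seq_len(n)),
    mate_id = NA_character_,
    mate_contig = NA_character_,
    extra_info = NA_character_
  )
}

vcf_header <- function(contigs = c(chr1 = 1000000, chr5 = 1000000)) {
  c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"l\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"m\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"ev\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
}

write_test_vcf <- function(body, path = withr::local_tempfile(fileext = ".vcf",
                                                              .local_envir = parent.frame()),
                           contigs = c(chr1 = 1000000, chr5 = 1000000)) {
  writeLines(c(vcf_header(contigs), body), path)
  path
}

# Oracle for neighbor grouping: iterated re-scan. Take the smallest
# unassigned position as an anchor; every unassigned record within the
# window of the anchor forms its group; repeat. Independent of the
# package's sequential sweep.
rescan_groups <- function(pos, window) {
  ord <- order(pos)
  gid <- integer(length(pos))
  g <- 0L
  remaining <- ord
  while (length(remaining)) {
    g <- g + 1L
    anchor <- pos[remaining[1]]
    in_group <- pos[remaining] - anchor <= window
    gid[remaining[in_group]] <- g
    remaining <- remaining[!in_group]
  }
  gid
}

# Oracle for matching: maximum bipartite matching cardinality via
# augmenting paths (Kuhn's algorithm) over the candidate-pair graph.
max_matching_tp <- function(truth_pos, test_pos, window = 500) {
  adj <- lapply(seq_along(truth_pos), function(i) {
    which(abs(truth_pos[i] - test_pos) <= window)
  })
  match_of <- rep(0L, length(test_pos))
  try_kuhn <- function(u, visited) {
    for (v in adj[[u]]) {
      if (!visited[v]) {
        visited[v] <- TRUE
        if (match_of[v] == 0L) {
          match_of[v] <<- u
          return(list(ok = TRUE, visited = visited))
        }
        res <- try_kuhn(match_of[v], visited)
        visited <- res$visited
        if (res$ok) {
          match_of[v] <<- u
          return(list(ok = TRUE, visited = visited))
        }
      }
    }
    list(ok = FALSE, visited = visited)
  }
  n <- 0L
  for (u in seq_along(truth_pos)) {
    if (try_kuhn(u, rep(FALSE, length(test_pos)))$ok) n <- n + 1L
  }
  n
}
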