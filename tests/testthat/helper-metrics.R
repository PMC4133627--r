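# Independent brute-force metric oracle: walks every unordered row pair
# column by column, mapping gapped columns to ungapped residue indices,
# without reusing the package's pair-key machinery.
brutePairs <- function(aln) {
  rows <- strsplit(unname(gappedRows(aln)), "")
  ids <- seqIds(aln)
  keys <- character()
  for (a in seq_along(rows)) for (b in seq_along(rows)) {
    if (a >= b) next
    ia <- 0L; ib <- 0L
    for (col in seq_along(rows[[a]])) {
      ca <- rows[[a]][col]; cb <- rows[[b]][col]
      if (ca != "-") ia <- ia + 1L
      if (cb != "-") ib <- ib + 1L
      if (ca != "-" && cb != "-") {
        pr <- sort(c(paste0(ids[a], ":", ia), paste0(ids[b], ":", ib)))
        keys <- c(keys, paste(pr, collapse = "|"))
      }
    }
  }
  unique(keys)
}

bruteScores <- function(test, ref) {
  pt <- brutePairs(test); pr <- brutePairs(ref)
  sig <- function(aln) {
    rows <- strsplit(unname(gappedRows(aln)), "")
    ids <- seqIds(aln)
    idx <- lapply(rows, function(r) cumsum(r != "-"))
    sapply(seq_along(rows[[1]]), function(col) {
      parts <- character()
      for (k in seq_along(rows))
        if (rows[[k]][col] != "-")
          parts <- c(parts, paste0(ids[k], ":", idx[[k]][col]))
      paste(sort(parts), collapse = "|")
    })
  }
  list(sp = length(intersect(pt, pr)) / length(pr),
       modeler = length(intersect(pt, pr)) / length(pt),
       tc = mean(sig(ref) %in% sig(test)))
}
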