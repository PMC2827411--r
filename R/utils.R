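# Internal helpers shared across modules.

# Convert 0-based half-open coordinates to IRanges (1-based closed).
ir0 <- function(starts, ends) {
  IRanges::IRanges(start = as.integer(starts) + 1L, end = as.integer(ends))
}

# Back to 0-based half-open.
from_ir <- function(x) {
  list(start = IRanges::start(x) - 1L, end = IRanges::end(x))
}

# Environment-based union-find avoids copy-on-write in tight loops.
make_uf <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  components <- function() {
    vapply(seq_len(n), find, integer(1))
  }
  list(find = find, union = union, components = components)
}

# Union all elements sharing a key: sort by key id and union consecutive
# elements within each run.
union_runs <- function(uf, key_id, owner) {
  if (length(key_id) < 2L) return(invisible(NULL))
  o <- order(key_id)
  k <- key_id[o]; w <- owner[o]
  same <- which(k[-1L] == k[-length(k)])
  for (i in same) uf$union(w[i], w[i + 1L])
  invisible(NULL)
}

# Merge 0-based half-open intervals into their set union (sorted, disjoint;
# touching intervals merge).  Base-R sweep: cheap enough for inner loops.
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) return(list(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  s <- as.integer(starts[o]); e <- as.integer(ends[o])
  cmax <- cummax(e)
  grp <- cumsum(c(TRUE, s[-1L] > cmax[-length(s)]))
  list(start = s[!duplicated(grp)],
       end = as.integer(unname(tapply(e, grp, max))))
}

# Do any of the intervals in a overlap (>= 1 base) any in b?  0-based
# half-open; plain arithmetic keeps this cheap inside pairwise loops.
intervals_overlap <- function(sa, ea, sb, eb) {
  if (length(sa) == 0L || length(sb) == 0L) return(FALSE)
  any(outer(sa, eb, `<`) & outer(ea, sb, `>`))
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# TSV I/O with '#'-prefixed provenance headers ------------------------------

write_tsv_header <- function(df, file, header_lines = character(0)) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

read_tsv_header <- function(file, colClasses = NA) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = colClasses, check.names = FALSE)
}

# Provenance header for every CLI/file output: version + parameter echo +
# md5 checksums of the inputs.  Deliberately no timestamps so that repeated
# runs on identical inputs are byte-identical.
provenance_header <- function(tool = "remapkit", params = list(),
                              inputs = character(0)) {
  ver <- as.character(utils::packageVersion("remapkit"))
  lines <- c(sprintf("%s %s", tool, ver),
             "coordinates: 0-based half-open")
  if (length(params)) {
    kv <- paste(names(params), vapply(params, function(x)
      paste(as.character(x), collapse = ","), character(1)),
      sep = "=", collapse = " ")
    lines <- c(lines, paste("params:", kv))
  }
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("input: %s md5=%s", basename(names(sums)), sums))
  }
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
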