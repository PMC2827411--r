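#' Gene-level signal from probe-set condition means
#'
#' The gene-level signal in a condition is the unweighted arithmetic mean of
#' the gene's probe-set signals in that condition.
#'
#' @param P numeric matrix of linear-scale signals, probe sets in rows,
#'   conditions in columns (replicates already averaged).
#' @return Named numeric vector of per-condition gene signals.
#' @export
gene_signal <- function(P) {
  P <- as.matrix(P)
  if (any(!is.finite(P)) || any(P <= 0))
    stop("signals must be strictly positive and finite")
  colMeans(P)
}

#' Splicing Index of one gene between two conditions
#'
#' For gene-level signal \eqn{G_x} (mean over the gene's probe sets) the
#' normalized intensity of probe set \eqn{i} in condition \eqn{x} is
#' \eqn{NI_{i,x} = P_{i,x} / G_x}, and the Splicing Index is
#' \eqn{SI_i = \log_2(NI_{i,1} / NI_{i,2})}.  The gene is called
#' alternatively spliced when any \eqn{|SI_i| \ge} `threshold`.
#'
#' @param P numeric matrix with exactly two columns (condition means,
#'   linear scale) and at least two probe-set rows.
#' @param threshold call threshold on |SI|, default 0.5.
#' @param log2_input if `TRUE`, `P` holds log2 signals and is exponentiated
#'   first.
#' @return List with `NI` (matrix), `SI` (vector), `called` (logical) and
#'   `gene_signal` (the two \eqn{G_x} values).
#' @export
splicing_index <- function(P, threshold = 0.5, log2_input = FALSE) {
  P <- as.matrix(P)
  if (ncol(P) != 2L) stop("splicing_index needs exactly two conditions")
  if (nrow(P) < 2L) stop("gene has fewer than two probe sets")
  if (log2_input) P <- 2^P
  G <- gene_signal(P)
  NI <- sweep(P, 2L, G, "/")
  SI <- log2(NI[, 1L] / NI[, 2L])
  list(NI = NI, SI = SI, called = any(abs(SI) >= threshold),
       gene_signal = G)
}

#' Splicing-Index calls for every multi-probe-set gene
#'
#' Condition means are computed from replicate columns first; genes with a
#' single probe set are skipped (their NI is identically 1 and SI 0, so
#' they cannot show a splicing signal) and reported with gene-level
#' expression only.
#'
#' @param expr numeric matrix, probe sets in rows (rownames = probe set
#'   IDs), samples in columns; strictly positive linear-scale intensities
#'   unless `log2_input`.
#' @param conditions character/factor of length `ncol(expr)` with exactly
#'   two levels assigning samples to conditions.
#' @param mapping data frame with columns `probe_set_id`, `gene_id`.
#' @param threshold call threshold on |SI|.
#' @param log2_input see [splicing_index()].
#' @return List with `calls` (per probe set: `gene_id`, `probe_set_id`,
#'   `NI1`, `NI2`, `SI`, `called`), `genes` (per gene: probe-set count,
#'   call, per-condition gene signal) and `skipped` (single-set genes).
#' @export
splice_calls <- function(expr, conditions, mapping, threshold = 0.5,
                         log2_input = FALSE) {
  expr <- as.matrix(expr)
  conditions <- as.factor(conditions)
  if (length(conditions) != ncol(expr))
    stop("conditions must label every sample column")
  if (nlevels(conditions) != 2L)
    stop("exactly two conditions required")
  if (!all(c("probe_set_id", "gene_id") %in% names(mapping)))
    stop("mapping needs columns probe_set_id and gene_id")
  if (log2_input) expr <- 2^expr
  if (any(!is.finite(expr)) || any(expr <= 0))
    stop("signals must be strictly positive and finite")
  lev <- levels(conditions)
  cm <- cbind(rowMeans(expr[, conditions == lev[1L], drop = FALSE]),
              rowMeans(expr[, conditions == lev[2L], drop = FALSE]))
  colnames(cm) <- lev
  known <- rownames(expr) %in% mapping$probe_set_id
  if (!all(known))
    stop("expression rows absent from mapping: ",
         paste(utils::head(rownames(expr)[!known], 3L), collapse = ", "))
  gene_of <- stats::setNames(mapping$gene_id, mapping$probe_set_id)
  by_gene <- split(rownames(expr), unname(gene_of[rownames(expr)]))

  calls <- list(); genes <- list(); skipped <- list()
  for (g in names(by_gene)) {
    ps <- by_gene[[g]]
    if (length(ps) < 2L) {
      skipped[[g]] <- data.frame(
        gene_id = g, probe_set_id = ps, reason = "single probe set",
        expr_1 = cm[ps, 1L], expr_2 = cm[ps, 2L], stringsAsFactors = FALSE)
      next
    }
    si <- splicing_index(cm[ps, , drop = FALSE], threshold = threshold)
    calls[[g]] <- data.frame(
      gene_id = g, probe_set_id = ps,
      NI1 = si$NI[, 1L], NI2 = si$NI[, 2L], SI = si$SI,
      called = si$called, stringsAsFactors = FALSE)
    genes[[g]] <- data.frame(
      gene_id = g, n_probe_sets = length(ps), called = si$called,
      gene_expr_1 = si$gene_signal[1L], gene_expr_2 = si$gene_signal[2L],
      stringsAsFactors = FALSE)
  }
  bind <- function(x) if (length(x)) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else NULL
  list(calls = bind(calls), genes = bind(genes), skipped = bind(skipped),
       threshold = threshold, conditions = lev)
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Validates the input and applies the standard step-up false discovery
#' rate adjustment (via [stats::p.adjust()]), preserving input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes by p-value and fold-change cutoffs
#'
#' A gene is selected when its adjusted p-value is strictly below
#' `p_thresh` and its fold change (\eqn{2^{log2fc}}) is at least
#' `fc_thresh` or at most `1/fc_thresh`.
#'
#' @param log2fc numeric vector of per-gene log2 fold changes.
#' @param adj_p adjusted p-values, same length and order.
#' @param gene_ids optional gene identifiers.
#' @param p_thresh significance cutoff (strict), default 0.05.
#' @param fc_thresh fold-change cutoff, default 2.
#' @return Data frame of the selected genes with a `direction` column
#'   (`"up"` / `"down"`).
#' @export
select_de <- function(log2fc, adj_p, gene_ids = NULL,
                      p_thresh = 0.05, fc_thresh = 2.0) {
  if (length(log2fc) != length(adj_p))
    stop("log2fc and adj_p have different lengths")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(log2fc))
  if (length(gene_ids) != length(log2fc))
    stop("gene_ids length mismatch")
  fc <- 2^log2fc
  sel <- adj_p < p_thresh & (fc >= fc_thresh | fc <= 1 / fc_thresh)
  data.frame(gene_id = gene_ids[sel], log2fc = log2fc[sel],
             adj_p = adj_p[sel],
             direction = ifelse(log2fc[sel] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Read an expression matrix with condition labels
#'
#' Expects a TSV whose first column is the probe-set ID and whose remaining
#' column names are `sample:condition` pairs.
#'
#' @param file path.
#' @return List with `expr` (matrix) and `conditions` (character vector).
#' @export
read_expression <- function(file) {
  df <- read_tsv_header(file)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  cn <- colnames(m)
  if (!all(grepl(":", cn)))
    stop("expression column names must be sample:condition")
  conditions <- sub("^.*:", "", cn)
  colnames(m) <- sub(":.*$", "", cn)
  list(expr = m, conditions = conditions)
}

#' Write an expression matrix with condition labels
#'
#' @param expr matrix with probe-set rownames.
#' @param conditions per-column condition labels.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_expression <- function(expr, conditions, file) {
  df <- data.frame(probe_set_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- paste(colnames(expr), conditions, sep = ":")
  write_tsv_header(df, file, provenance_header(params = list(
    samples = ncol(expr), probe_sets = nrow(expr))))
}
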