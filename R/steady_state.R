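#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated proteinGroups file and extracts the columns used
#' downstream: per-sample `LFQ intensity <sample>` and `iBAQ <sample>`
#' intensities, `Peptides`, `Unique peptides`, and the `Reverse` and
#' `Only identified by site` flags (`"+"` marks a flagged row). Zero
#' intensities are converted to `NA` (not quantified).
#'
#' @param path TSV file path.
#' @return A list with `ids`, `lfq` (matrix proteins x samples), `ibaq`
#'   (matrix), `peptides`, `unique_peptides`, `reverse`,
#'   `only_by_site` and `samples`.
#' @export
read_protein_groups <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("Protein IDs", "Peptides", "Unique peptides")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("proteinGroups file lacks columns: ", paste(miss, collapse = ", "))
  lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  ibaq_cols <- grep("^iBAQ ", names(tab), value = TRUE)
  ibaq_cols <- ibaq_cols[!grepl("^iBAQ [LH] ", ibaq_cols)]
  grab <- function(cols, prefix) {
    m <- as.matrix(tab[, cols, drop = FALSE])
    m[m == 0] <- NA
    colnames(m) <- sub(prefix, "", cols)
    rownames(m) <- tab[["Protein IDs"]]
    m
  }
  flag <- function(col) if (col %in% names(tab))
    !is.na(tab[[col]]) & tab[[col]] == "+" else rep(FALSE, nrow(tab))
  list(ids = tab[["Protein IDs"]],
       lfq = grab(lfq_cols, "^LFQ intensity "),
       ibaq = grab(ibaq_cols, "^iBAQ "),
       peptides = tab[["Peptides"]],
       unique_peptides = tab[["Unique peptides"]],
       reverse = flag("Reverse"),
       only_by_site = flag("Only identified by site"),
       samples = sub("^LFQ intensity ", "", lfq_cols))
}

#' Acceptance filter for identified proteins
#'
#' Keeps proteins that (a) are not flagged as only identified by site,
#' (b) do not match the reverse (decoy) database, (c) have more than one
#' peptide assigned of which at least one is unique, and (d) — for
#' steady-state replicate designs — are quantified in at least
#' `min_replicates` replicates of at least one condition.
#'
#' @param pg a list as returned by [read_protein_groups()].
#' @param condition_of named character vector mapping sample name to
#'   condition label; `NULL` skips the replicate criterion.
#' @param min_replicates replicate threshold (default 2).
#' @return A list: the filtered `pg` plus `drop_reasons`, a named count of
#'   proteins removed per criterion (a protein counts under every criterion
#'   it fails).
#' @export
acceptance_filter <- function(pg, condition_of = NULL, min_replicates = 2L) {
  n <- length(pg$ids)
  bad_site <- pg$only_by_site
  bad_rev <- pg$reverse
  bad_pep <- !(pg$peptides > 1 & pg$unique_peptides >= 1)
  bad_rep <- rep(FALSE, n)
  if (!is.null(condition_of)) {
    miss <- setdiff(colnames(pg$lfq), names(condition_of))
    if (length(miss))
      stop("no condition given for sample(s): ", paste(miss, collapse = ", "))
    conds <- unique(condition_of[colnames(pg$lfq)])
    quant_per_cond <- sapply(conds, function(cc) {
      cols <- colnames(pg$lfq)[condition_of[colnames(pg$lfq)] == cc]
      rowSums(!is.na(pg$lfq[, cols, drop = FALSE]))
    })
    bad_rep <- apply(quant_per_cond < min_replicates, 1, all)
  }
  keep <- !(bad_site | bad_rev | bad_pep | bad_rep)
  out <- pg
  for (f in c("ids", "peptides", "unique_peptides", "reverse",
              "only_by_site"))
    out[[f]] <- pg[[f]][keep]
  out$lfq <- pg$lfq[keep, , drop = FALSE]
  out$ibaq <- pg$ibaq[keep, , drop = FALSE]
  out$drop_reasons <- c(only_by_site = sum(bad_site),
                        reverse = sum(bad_rev),
                        peptide_criteria = sum(bad_pep),
                        replicate_coverage = sum(bad_rep))
  out
}

#' Impute missing log10 intensities from a downshifted normal
#'
#' Missing values are drawn per sample (column) from a normal distribution
#' whose mean is the observed sample mean shifted down by `downshift` sample
#' standard deviations and whose standard deviation is `width` times the
#' sample standard deviation — the standard transformation used to place
#' imputed values near the detection limit. Observed values are never
#' altered.
#'
#' @param mat matrix of log10 intensities (proteins x samples), `NA` for
#'   missing.
#' @param seed random seed.
#' @param width,downshift imputation parameters (defaults 0.3 and 1.8).
#' @return The completed matrix.
#' @export
impute_missing <- function(mat, seed = 1L, width = 0.3, downshift = 1.8) {
  set.seed(seed)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j][!is.na(mat[, j])]
    nmiss <- sum(is.na(mat[, j]))
    if (nmiss == 0L) next
    if (length(obs) < 2L)
      stop("sample ", colnames(mat)[j],
           " has fewer than 2 observed values; cannot impute")
    mu <- mean(obs) - downshift * stats::sd(obs)
    sd_imp <- width * stats::sd(obs)
    out[is.na(mat[, j]), j] <- stats::rnorm(nmiss, mu, sd_imp)
  }
  out
}

#' Fold-change differential expression calls
#'
#' Compares two conditions on mean log10 LFQ intensity per protein. The
#' linear fold change is `10^(mean_A - mean_B)`; a protein is differential
#' when the fold change exceeds `cutoff` in either direction.
#'
#' @param mat complete matrix of log10 intensities (proteins x samples).
#' @param condition_of named character vector sample -> condition.
#' @param condition_a,condition_b condition labels to compare (A over B).
#' @param cutoff linear fold-change threshold (default 5).
#' @return A data.frame: `protein`, `mean_log10_a`, `mean_log10_b`,
#'   `fold_change`, `is_differential`.
#' @export
fold_change_de <- function(mat, condition_of, condition_a, condition_b,
                           cutoff = 5) {
  conds <- condition_of[colnames(mat)]
  if (!condition_a %in% conds) stop("unknown condition: ", condition_a)
  if (!condition_b %in% conds) stop("unknown condition: ", condition_b)
  ma <- rowMeans(mat[, conds == condition_a, drop = FALSE])
  mb <- rowMeans(mat[, conds == condition_b, drop = FALSE])
  fc <- 10^(ma - mb)
  data.frame(protein = rownames(mat), mean_log10_a = ma, mean_log10_b = mb,
             fold_change = fc,
             is_differential = fc >= cutoff | fc <= 1 / cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative iBAQ per sample
#'
#' Divides each protein's iBAQ by the summed iBAQ of its sample, giving the
#' proteome fraction; `NA` intensities count as zero signal.
#'
#' @param ibaq matrix (proteins x samples).
#' @return Matrix of the same shape; columns sum to 1.
#' @export
relative_ibaq <- function(ibaq) {
  m <- ibaq
  m[is.na(m)] <- 0
  sweep(m, 2, colSums(m), "/")
}

#' Correlate summed class abundance with growth rate
#'
#' Sums the relative iBAQ of the proteins in each class per sample and
#' correlates the summed proteome fraction with the per-sample growth rate
#' (Pearson).
#'
#' @param ibaq iBAQ matrix (proteins x samples), rownames are protein ids.
#' @param class_map data.frame with columns `protein_id`, `class` (a protein
#'   may appear under several classes).
#' @param growth_rates named numeric vector, one rate per sample.
#' @return A data.frame with one row per class: summed fraction per sample
#'   (columns `fraction.<sample>`), `correlation`, `n_samples`. Correlation
#'   is `NA` with fewer than 3 samples or zero variance.
#' @export
class_growth_correlation <- function(ibaq, class_map, growth_rates) {
  rel <- relative_ibaq(ibaq)
  miss <- setdiff(colnames(rel), names(growth_rates))
  if (length(miss))
    stop("no growth rate for sample(s): ", paste(miss, collapse = ", "))
  mu <- growth_rates[colnames(rel)]
  out <- lapply(split(class_map$protein_id, class_map$class), function(ids) {
    frac <- colSums(rel[rownames(rel) %in% ids, , drop = FALSE])
    tol <- 1e-10 * max(abs(frac), 1)   # guard against roundoff "variance"
    r <- if (length(frac) >= 3 && stats::sd(frac) > tol && stats::sd(mu) > 0)
      stats::cor(frac, mu) else NA_real_
    c(frac, correlation = r, n_samples = length(frac))
  })
  res <- as.data.frame(do.call(rbind, out))
  names(res)[seq_len(ncol(rel))] <- paste0("fraction.", colnames(rel))
  res$class <- rownames(res)
  rownames(res) <- NULL
  res[, c("class", setdiff(names(res), "class"))]
}
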