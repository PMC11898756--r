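# in-code construction of a small proteinGroups-style table
make_pg <- function() {
  samples <- c("glc_1", "glc_2", "gal_1", "gal_2")
  lfq <- rbind(
    A = c(1e8, 1.2e8, 2e6, 2.4e6),     # strongly higher on glucose
    B = c(5e6, 6e6, 5.5e6, 6.5e6),     # unchanged
    C = c(3e7, NA, NA, 4e6),           # one replicate per condition
    D = c(2e7, 3e7, 1e7, 2e7),         # flagged reverse
    E = c(8e6, 9e6, 7e6, NA))          # 2 peptides, 0 unique
  colnames(lfq) <- samples
  list(ids = rownames(lfq), lfq = lfq, ibaq = lfq / 10,
       peptides = c(5, 4, 6, 3, 2),
       unique_peptides = c(3, 2, 4, 2, 0),
       reverse = c(FALSE, FALSE, FALSE, TRUE, FALSE),
       only_by_site = rep(FALSE, 5),
       samples = samples)
}
cond <- c(glc_1 = "glc", glc_2 = "glc", gal_1 = "gal", gal_2 = "gal")

test_that("acceptance filter applies all four criteria with logged reasons", {
  pg <- make_pg()
  out <- acceptance_filter(pg, condition_of = cond)
  expect_setequal(out$ids, c("A", "B"))
  expect_equal(unname(out$drop_reasons["reverse"]), 1)
  expect_equal(unname(out$drop_reasons["peptide_criteria"]), 1)
  expect_equal(unname(out$drop_reasons["replicate_coverage"]), 1)
  # without the replicate criterion, C survives
  expect_true("C" %in% acceptance_filter(pg)$ids)
  expect_error(acceptance_filter(pg, condition_of = cond[1:3]), "condition")
})

test_that("imputation draws from the downshifted normal and never touches data", {
  set.seed(1)
  big <- matrix(rnorm(20000, mean = 8, sd = 1), ncol = 2,
                dimnames = list(NULL, c("s1", "s2")))
  miss <- big
  miss[sample(10000, 5000), 1] <- NA
  out <- impute_missing(miss, seed = 7)
  imputed <- out[is.na(miss[, 1]), 1]
  obs <- miss[!is.na(miss[, 1]), 1]
  expect_lt(abs(mean(imputed) - (mean(obs) - 1.8 * sd(obs))), 0.1)
  expect_lt(abs(sd(imputed) - 0.3 * sd(obs)), 0.05)
  expect_identical(out[!is.na(miss[, 1]), 1], obs)
  expect_identical(out[, 2], miss[, 2])
  expect_identical(impute_missing(miss, seed = 7), out)
  expect_identical(impute_missing(big, seed = 3), big)  # nothing to impute
  thin <- matrix(c(1, NA, NA, NA), ncol = 1,
                 dimnames = list(NULL, "s"))
  expect_error(impute_missing(thin), "fewer than 2")
})

test_that("fold changes follow 10^(mean difference) with threshold semantics", {
  m <- rbind(same = c(7, 7, 7, 7),
             up = c(7.7, 7.7, 7.0, 7.0),
             mid = c(7.477, 7.477, 7.0, 7.0))  # ~3-fold
  colnames(m) <- names(cond)
  de <- fold_change_de(m, cond, "glc", "gal", cutoff = 5)
  expect_equal(de$fold_change[1], 1)
  expect_false(de$is_differential[1])
  expect_equal(de$fold_change[2], 10^0.7, tolerance = 1e-12)
  expect_true(de$is_differential[2])            # 5.01 >= 5
  expect_false(de$is_differential[3])           # 3-fold under cutoff 5
  expect_true(fold_change_de(m, cond, "glc", "gal",
                             cutoff = 2)$is_differential[3])
  expect_error(fold_change_de(m, cond, "glc", "lactose"), "unknown")
})

test_that("A-over-B fold changes are reciprocals of B-over-A", {
  set.seed(9)
  m <- matrix(rnorm(40, 7), ncol = 4, dimnames = list(paste0("p", 1:10),
                                                      names(cond)))
  ab <- fold_change_de(m, cond, "glc", "gal")
  ba <- fold_change_de(m, cond, "gal", "glc")
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-9)
})

test_that("relative iBAQ columns sum to one and class fractions track growth", {
  set.seed(13)
  ibaq <- matrix(rlnorm(60, 10), ncol = 4,
                 dimnames = list(paste0("p", 1:15), names(cond)))
  rel <- relative_ibaq(ibaq)
  expect_equal(unname(colSums(rel)), rep(1, 4), tolerance = 1e-9)
  # class = all proteins: fraction 1 everywhere, correlation undefined
  all_map <- data.frame(protein_id = rownames(ibaq), class = "all")
  mu <- c(glc_1 = 0.64, glc_2 = 0.64, gal_1 = 0.24, gal_2 = 0.24)
  prof <- class_growth_correlation(ibaq, all_map, mu)
  expect_equal(unname(unlist(prof[1, paste0("fraction.", names(cond))])),
               rep(1, 4), tolerance = 1e-9)
  expect_true(is.na(prof$correlation[1]))
  # construct a class whose fraction is exactly linear in growth rate
  ib2 <- ibaq
  target <- 0.1 + 0.2 * mu
  csum <- colSums(ib2[1:5, ]); tot <- colSums(ib2)
  scale <- target * (tot - csum) / (csum * (1 - target))
  ib2[1:5, ] <- sweep(ib2[1:5, ], 2, scale, "*")
  map5 <- data.frame(protein_id = rownames(ibaq)[1:5], class = "lin")
  prof2 <- class_growth_correlation(ib2, map5, mu)
  expect_equal(prof2$correlation[1], 1, tolerance = 1e-9)
})

test_that("random class membership shows no systematic growth correlation", {
  set.seed(17)
  mu <- c(a = 0.2, b = 0.35, c = 0.5, d = 0.65)
  cors <- replicate(20, {
    ibaq <- matrix(rlnorm(200, 10), ncol = 4,
                   dimnames = list(paste0("p", 1:50), names(mu)))
    map <- data.frame(protein_id = sample(rownames(ibaq), 10),
                      class = "rand")
    class_growth_correlation(ibaq, map, mu)$correlation[1]
  })
  # permutation null: mean |r| for n = 4 samples is high by chance alone,
  # but the signed mean must hover near zero
  expect_lt(abs(mean(cors)), 0.3)
})

test_that("proteinGroups TSV reader extracts intensities and flags", {
  tsv <- withr::local_tempfile(fileext = ".txt")
  hdr <- c("Protein IDs", "Peptides", "Unique peptides",
           "LFQ intensity glc_1", "LFQ intensity gal_1",
           "iBAQ glc_1", "iBAQ gal_1", "Reverse",
           "Only identified by site")
  rows <- list(c("prot1", "5", "3", "1e8", "2e6", "1e7", "2e5", "", ""),
               c("REV__x", "2", "1", "1e5", "1e5", "1e4", "1e4", "+", ""),
               c("prot2", "3", "2", "0", "4e6", "0", "4e5", "", ""))
  writeLines(c(paste(hdr, collapse = "\t"),
               sapply(rows, paste, collapse = "\t")), tsv)
  pg <- read_protein_groups(tsv)
  expect_equal(pg$samples, c("glc_1", "gal_1"))
  expect_true(pg$reverse[2])
  expect_true(is.na(pg$lfq["prot2", "glc_1"]))   # zero -> not quantified
  expect_equal(pg$lfq["prot1", "glc_1"], 1e8)
  expect_equal(pg$ibaq["prot1", "gal_1"], 2e5)
})
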