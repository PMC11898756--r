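#' In-silico tryptic digestion (trypsin/P)
#'
#' Cleaves after every K or R with no proline exception and returns all
#' peptides with up to `max_missed` internal missed cleavage sites, dropping
#' peptides shorter than `min_len`.
#'
#' @param sequence one amino-acid sequence (uppercase, 20 residues plus X).
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_len minimum peptide length retained (default 7).
#' @param accession parent accession recorded on each peptide.
#' @return A data.frame with columns `sequence`, `accession`, `start`, `end`
#'   (1-based inclusive), `missed_cleavages`, `has_lysine`,
#'   `is_protein_cterm`.
#' @export
#' @examples
#' tryptic_digest("AAAAAAKGGGGGGR", max_missed = 0)$sequence
tryptic_digest <- function(sequence, max_missed = 2L, min_len = 7L,
                           accession = "protein") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop("sequence contains characters outside the amino-acid alphabet")
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  # cut points: after each K/R, plus the protein C-terminus
  cuts <- c(which(res %in% c("K", "R")), n)
  cuts <- sort(unique(cuts[cuts <= n]))
  starts <- c(1L, cuts[-length(cuts)] + 1L)
  starts <- starts[starts <= n]
  ends <- cuts[seq_along(starts)]
  nfrag <- length(starts)

  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      s <- starts[i]; e <- ends[j]
      if (e - s + 1L < min_len) next
      pep <- substr(sequence, s, e)
      out[[length(out) + 1L]] <- data.frame(
        sequence = pep, accession = accession, start = s, end = e,
        missed_cleavages = m,
        has_lysine = grepl("K", pep, fixed = TRUE),
        is_protein_cterm = (e == n),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(sequence = character(0), accession = character(0),
                      start = integer(0), end = integer(0),
                      missed_cleavages = integer(0), has_lysine = logical(0),
                      is_protein_cterm = logical(0)))
  do.call(rbind, out)
}

# fully-cleaved fragments (missed_cleavages = 0, no length filter) in order
fully_cleaved_fragments <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cuts <- sort(unique(c(which(res %in% c("K", "R")), n)))
  starts <- c(1L, cuts[-length(cuts)] + 1L)
  starts <- starts[starts <= n]
  ends <- cuts[seq_along(starts)]
  data.frame(start = starts, end = ends,
             sequence = substring(sequence, starts, ends),
             stringsAsFactors = FALSE)
}

#' Build the artificial-protein database of lysine-free tryptic peptides
#'
#' In a heavy-lysine pulse experiment only lysine-containing peptides carry
#' the label, so peptides without lysine must not drive quantification. This
#' builder collects all lysine-free fully-cleaved tryptic fragments,
#' concatenates them into "artificial proteins", and thereby makes every
#' lysine-free peptide non-unique in a search against original + artificial
#' databases. Runs of fragments that are consecutive in the source protein
#' are kept adjacent and in source order, so the search engine's own digest
#' of an artificial entry regenerates the missed-cleavage lysine-free
#' variants as well. A fragment that forms the protein C-terminus closes its
#' artificial entry, so its C-terminal position is respected. Entries are
#' chunked at roughly `chunk` residues with accessions `ART_000001`, ...
#'
#' @param proteome named character vector (or `Biostrings::AAStringSet`) of
#'   protein sequences; names are accessions.
#' @param chunk target maximum entry length in residues (default 5000; a
#'   single run longer than this is kept whole).
#' @return An object of class `"artificial_db"`: list with `entries` (named
#'   character vector of artificial sequences) and `provenance` (data.frame
#'   mapping every member peptide to its source accession, source positions,
#'   artificial accession and position within it).
#' @export
build_artificial_db <- function(proteome, chunk = 5000L) {
  proteome <- as_aa_character(proteome)
  if (length(proteome) == 0L) stop("empty proteome")

  # per protein: maximal runs of consecutive K-free fully-cleaved fragments
  blocks <- list()   # each: list(seq, prov = data.frame, cterm = flag)
  for (acc in names(proteome)) {
    fr <- fully_cleaved_fragments(proteome[[acc]])
    kfree <- !grepl("K", fr$sequence, fixed = TRUE)
    if (!any(kfree)) next
    run_id <- cumsum(c(TRUE, diff(which(kfree)) != 1L))
    idx <- which(kfree)
    for (r in unique(run_id)) {
      sel <- idx[run_id == r]
      blocks[[length(blocks) + 1L]] <- list(
        seq = paste(fr$sequence[sel], collapse = ""),
        prov = data.frame(peptide = fr$sequence[sel],
                          source_accession = acc,
                          source_start = fr$start[sel],
                          source_end = fr$end[sel],
                          stringsAsFactors = FALSE),
        cterm = fr$end[sel[length(sel)]] == nchar(proteome[[acc]]))
    }
  }
  entries <- character(0)
  prov <- list()
  cur_seq <- ""
  cur_prov <- list()
  flush <- function() {
    if (nchar(cur_seq) == 0L) return()
    acc <- sprintf("ART_%06d", length(entries) + 1L)
    entries[[acc]] <<- cur_seq
    p <- do.call(rbind, cur_prov)
    p$art_accession <- acc
    prov[[length(prov) + 1L]] <<- p
    cur_seq <<- ""
    cur_prov <<- list()
  }
  for (b in blocks) {
    if (nchar(cur_seq) > 0L && nchar(cur_seq) + nchar(b$seq) > chunk) flush()
    off <- nchar(cur_seq)
    bp <- b$prov
    bp$art_start <- off + c(0L, cumsum(nchar(bp$peptide))[-nrow(bp)]) + 1L
    bp$art_end <- off + cumsum(nchar(bp$peptide))
    cur_seq <- paste0(cur_seq, b$seq)
    cur_prov[[length(cur_prov) + 1L]] <- bp
    # a block carrying a protein C-terminus must stay terminal in its entry
    if (b$cterm) flush()
  }
  flush()
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(peptide = character(0), source_accession = character(0),
               source_start = integer(0), source_end = integer(0),
               art_accession = character(0), art_start = integer(0),
               art_end = integer(0))
  rownames(provenance) <- NULL
  structure(list(entries = entries, provenance = provenance),
            class = "artificial_db")
}

as_aa_character <- function(x) {
  if (inherits(x, "AAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("proteome must be character or an AAStringSet")
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("proteome sequences must be named by accession")
  toupper(x)
}

#' Check that lysine-free peptides lost uniqueness
#'
#' Verifies the artificial database against the original proteome: every
#' lysine-free tryptic peptide (up to `max_missed` missed cleavages, length
#' >= `min_len`) must occur in at least two entries of the combined
#' original+artificial database, so a search engine will not treat it as
#' unique; and no lysine-containing peptide may match an artificial entry
#' (artificial entries contain no lysine by construction, so a collision
#' marks a corrupted database).
#'
#' @param proteome named character vector (or `AAStringSet`) of original
#'   proteins.
#' @param db an `"artificial_db"` from [build_artificial_db()].
#' @param max_missed,min_len digestion settings (defaults 2 and 7).
#' @return A list: `n_kfree_peptides`, `n_duplicated`, `duplication_rate`,
#'   `missing_peptides` (K-free peptides not recovered in any artificial
#'   entry), `k_collisions` (must be empty), and `ok`.
#' @export
verify_quantification_uniqueness <- function(proteome, db, max_missed = 2L,
                                             min_len = 7L) {
  proteome <- as_aa_character(proteome)
  peps <- do.call(rbind, lapply(names(proteome), function(acc)
    tryptic_digest(proteome[[acc]], max_missed, min_len, accession = acc)))
  if (is.null(peps) || nrow(peps) == 0L)
    return(list(n_kfree_peptides = 0L, n_duplicated = 0L,
                duplication_rate = NA_real_,
                missing_peptides = character(0),
                k_collisions = character(0), ok = TRUE))
  art <- unname(db$entries)
  in_artificial <- function(p) any(grepl(p, art, fixed = TRUE))

  kfree <- unique(peps$sequence[!peps$has_lysine])
  dup <- vapply(kfree, in_artificial, logical(1))
  kcont <- unique(peps$sequence[peps$has_lysine])
  collisions <- kcont[vapply(kcont, in_artificial, logical(1))]
  if (length(collisions))
    stop("lysine-containing peptide(s) collide with artificial entries: ",
         paste(utils::head(collisions, 5), collapse = ", "))
  list(n_kfree_peptides = length(kfree),
       n_duplicated = sum(dup),
       duplication_rate = if (length(kfree)) mean(dup) else NA_real_,
       missing_peptides = kfree[!dup],
       k_collisions = collisions,
       ok = length(kfree) == 0L || all(dup))
}

#' Write an artificial-protein database as FASTA with a provenance sidecar
#'
#' @param db an `"artificial_db"`.
#' @param fasta_path output FASTA path (60-column wrapped).
#' @param provenance_path optional TSV path for the peptide provenance map.
#' @return `fasta_path`, invisibly.
#' @export
write_artificial_db <- function(db, fasta_path, provenance_path = NULL) {
  aa <- Biostrings::AAStringSet(db$entries)
  Biostrings::writeXStringSet(aa, fasta_path, width = 60L)
  if (!is.null(provenance_path))
    utils::write.table(db$provenance, provenance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a protein FASTA as a named character vector
#'
#' Thin wrapper over `Biostrings::readAAStringSet` that returns plain named
#' sequences with the accession (first whitespace-separated token) as name.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}
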