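#' Amino-acid alignment objects
#'
#' An `rs_alignment` is a taxa-by-sites character matrix over the 20-state
#' amino-acid alphabet (or the 6-state Dayhoff alphabet after recoding), with
#' `-` for gaps and `X` for missing/ambiguous residues.  Gaps and `X` are
#' treated identically throughout the package: excluded from all frequency
#' counts and treated as total uncertainty in likelihood computations.
#'
#' @param mat character matrix; rownames are taxon labels.
#' @param alphabet `"aa"` (20 states) or `"dayhoff6"` (digit states 1-6).
#' @param partition optional data.frame with columns `gene`, `start`, `end`
#'   giving 0-based half-open column ranges that tile the alignment.
#' @return an object of class `rs_alignment`.
#' @export
new_alignment <- function(mat, alphabet = "aa", partition = NULL) {
  if (!is.matrix(mat) || !is.character(mat))
    stop("mat must be a character matrix")
  taxa <- rownames(mat)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("taxon labels must be non-empty rownames")
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1])
  valid <- c(alphabet_states(alphabet), "-", "X")
  bad <- setdiff(unique(as.vector(mat)), valid)
  if (length(bad))
    stop("invalid state code(s): ", paste(bad, collapse = " "))
  if (!is.null(partition)) {
    partition <- as.data.frame(partition)
    stopifnot(all(c("gene", "start", "end") %in% names(partition)))
    o <- order(partition$start)
    partition <- partition[o, , drop = FALSE]
    rownames(partition) <- NULL
    if (nrow(partition)) {
      ok <- partition$start[1] == 0 &&
        partition$end[nrow(partition)] == ncol(mat) &&
        all(partition$start[-1] == partition$end[-nrow(partition)])
      if (!ok) stop("partition ranges must tile [0, n_sites) without overlap")
    }
  }
  structure(list(mat = mat, alphabet = alphabet, partition = partition),
            class = "rs_alignment")
}

#' @export
print.rs_alignment <- function(x, ...) {
  cat(sprintf("rs_alignment: %d taxa x %d sites (%s alphabet)%s\n",
              nrow(x$mat), ncol(x$mat), x$alphabet,
              if (is.null(x$partition)) ""
              else sprintf(", %d partitions", nrow(x$partition))))
  invisible(x)
}

#' @rdname new_alignment
#' @param aln an `rs_alignment`.
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' @rdname new_alignment
#' @export
n_taxa <- function(aln) nrow(aln$mat)

#' @rdname new_alignment
#' @export
taxa_names <- function(aln) rownames(aln$mat)

# integer encoding for the likelihood engine: 0-based, -1 = gap/missing
alignment_states_int <- function(aln) {
  states <- alphabet_states(aln$alphabet)
  m <- match(aln$mat, states) - 1L
  m[is.na(m)] <- -1L
  matrix(m, nrow = nrow(aln$mat), dimnames = dimnames(aln$mat))
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' Sequences are upper-cased; letters outside the alphabet (for amino acids,
#' anything but the 20 one-letter codes and `-`) become `X` (missing).
#' Lines starting with `;` are skipped in FASTA input.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (relaxed, sequential).
#' @param alphabet `"aa"` or `"dayhoff6"`.
#' @return an [new_alignment()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           alphabet = "aa") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    seqs <- tryCatch(
      seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                         forceDNAtolower = FALSE),
      error = function(e) stop("empty or malformed alignment file: ", path))
    if (!length(seqs)) stop("empty or malformed alignment file: ", path)
    labs <- names(seqs)
    strs <- toupper(vapply(seqs, function(s) as.character(s)[1], ""))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty alignment file: ", path)
    hdr <- scan(text = lines[1], what = integer(), n = 2, quiet = TRUE)
    if (length(hdr) != 2) stop("malformed PHYLIP header")
    body <- lines[-1]
    if (length(body) != hdr[1]) stop("PHYLIP taxon count mismatch")
    labs <- sub("\\s.*$", "", body)
    strs <- toupper(gsub("\\s", "", sub("^\\S+\\s+", "", body)))
    if (any(nchar(strs) != hdr[2])) stop("PHYLIP sequence length mismatch")
  }
  if (anyDuplicated(labs))
    stop("duplicate taxon label: ", labs[duplicated(labs)][1])
  lens <- nchar(strs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths differ")
  mat <- do.call(rbind, strsplit(strs, ""))
  rownames(mat) <- labs
  valid <- c(alphabet_states(alphabet), "-")
  mat[!(mat %in% valid)] <- "X"
  new_alignment(mat, alphabet = alphabet)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' Output is byte-stable: identical input always yields identical bytes.
#' Dayhoff-6 recoded alignments written as FASTA carry a leading `;` comment
#' documenting the digit codes.
#'
#' @inheritParams read_alignment
#' @param aln an `rs_alignment`.
#' @return the path, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  if (format == "fasta") {
    out <- character(0)
    if (aln$alphabet == "dayhoff6")
      out <- "; dayhoff6 states: 1=AGPST 2=DENQ 3=HKR 4=ILMV 5=FWY 6=C"
    out <- c(out, as.vector(rbind(paste0(">", names(seqs)), seqs)))
  } else {
    out <- c(sprintf("%d %d", n_taxa(aln), n_sites(aln)),
             sprintf("%s  %s", names(seqs), seqs))
  }
  con <- file(path, "wb")  # binary mode: no platform newline surprises
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa absent from a gene are filled with `X` across that gene's range.
#' The partition map records each gene's 0-based half-open column range.
#'
#' @param alignments list of `rs_alignment` objects sharing one alphabet.
#' @param gene_ids character vector of gene names (default `g1`, `g2`, ...).
#' @return a single `rs_alignment` with a partition map.
#' @export
concatenate_alignments <- function(alignments,
                                   gene_ids = paste0("g", seq_along(alignments))) {
  stopifnot(length(alignments) >= 1)
  alpha <- unique(vapply(alignments, function(a) a$alphabet, ""))
  if (length(alpha) != 1) stop("conflicting alphabets")
  taxa <- unique(unlist(lapply(alignments, taxa_names)))
  lens <- vapply(alignments, n_sites, 0L)
  total <- sum(lens)
  mat <- matrix("X", length(taxa), total, dimnames = list(taxa, NULL))
  at <- 0L
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    mat[taxa_names(a), (at + 1L):(at + lens[i])] <- a$mat
    at <- at + lens[i]
  }
  ends <- cumsum(lens)
  part <- data.frame(gene = gene_ids, start = ends - lens, end = ends,
                     stringsAsFactors = FALSE)
  new_alignment(mat, alphabet = alpha, partition = part)
}

#' Jackknife alignment sites
#'
#' Samples `m` columns uniformly without replacement and returns them in
#' ascending original order; the partition map is dropped.
#'
#' @param aln an `rs_alignment`.
#' @param m number of columns to keep.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @export
jackknife_sites <- function(aln, m, seed) {
  if (m < 1 || m > n_sites(aln)) stop("m must be in [1, n_sites]")
  idx <- sort(with_seed(seed, sample.int(n_sites(aln), m, replace = FALSE)))
  new_alignment(aln$mat[, idx, drop = FALSE], alphabet = aln$alphabet)
}

#' Dayhoff-6 recoding
#'
#' Maps the 20 amino acids onto the six Dayhoff exchange groups
#' (AGPST, DENQ, HKR, ILMV, FWY, C), written as digit states 1-6.
#' Gaps and missing cells are preserved.
#'
#' @param aln a 20-state `rs_alignment`.
#' @export
recode_dayhoff6 <- function(aln) {
  if (aln$alphabet != "aa") stop("alignment is already recoded")
  map <- character(0)
  for (g in names(DAYHOFF6_GROUPS)) map[DAYHOFF6_GROUPS[[g]]] <- g
  map["-"] <- "-"; map["X"] <- "X"
  mat <- matrix(map[aln$mat], nrow = nrow(aln$mat),
                dimnames = dimnames(aln$mat))
  new_alignment(mat, alphabet = "dayhoff6", partition = aln$partition)
}

#' Remove taxa from an alignment
#'
#' Rows are dropped; columns are untouched (no re-masking).  At least four
#' taxa must remain.
#'
#' @param aln an `rs_alignment`.
#' @param taxa taxon labels to remove.
#' @export
remove_taxa <- function(aln, taxa) {
  unknown <- setdiff(taxa, taxa_names(aln))
  if (length(unknown)) stop("unknown taxon name: ", unknown[1])
  keep <- setdiff(taxa_names(aln), taxa)
  if (length(keep) < 4) stop("fewer than 4 taxa would remain")
  new_alignment(aln$mat[keep, , drop = FALSE], alphabet = aln$alphabet,
                partition = aln$partition)
}

#' Empirical state frequencies
#'
#' Gaps and missing cells are excluded from counts.  An optional pseudocount
#' is added to every state before normalization.
#'
#' @param aln an `rs_alignment`.
#' @param per_taxon if `TRUE`, return a taxa x states matrix.
#' @param pseudocount non-negative pseudocount per state (default 0).
#' @return a named frequency vector, or matrix when `per_taxon`.
#' @export
empirical_frequencies <- function(aln, per_taxon = FALSE, pseudocount = 0) {
  states <- alphabet_states(aln$alphabet)
  if (per_taxon) {
    cnt <- t(apply(aln$mat, 1, function(r)
      tabulate(match(r, states), nbins = length(states))))
    if (any(rowSums(cnt) == 0 & pseudocount == 0))
      stop("taxon with zero counted cells: ",
           taxa_names(aln)[rowSums(cnt) == 0][1])
    cnt <- cnt + pseudocount
    f <- cnt / rowSums(cnt)
    dimnames(f) <- list(taxa_names(aln), states)
    f
  } else {
    cnt <- tabulate(match(aln$mat, states), nbins = length(states))
    if (sum(cnt) == 0 && pseudocount == 0)
      stop("no counted (non-gap, non-missing) cells")
    cnt <- cnt + pseudocount
    setNames(cnt / sum(cnt), states)
  }
}

#' Mean per-site amino-acid diversity (div)
#'
#' The average over columns of the number of distinct observed residues
#' (gaps/missing excluded); an all-gap column contributes 0.
#'
#' @param aln an `rs_alignment`.
#' @return a single number in `[0, alphabet size]`.
#' @export
diversity_statistic <- function(aln) {
  if (n_sites(aln) == 0) stop("empty alignment")
  states <- alphabet_states(aln$alphabet)
  m <- alignment_states_int(aln)
  present <- vapply(seq_along(states) - 1L,
                    function(st) .colSums(m == st, nrow(m), ncol(m)) > 0,
                    logical(ncol(m)))
  present <- matrix(present, ncol(m), length(states))
  mean(.rowSums(present, ncol(m), length(states)))
}

#' Maximum squared compositional deviation (MAX)
#'
#' The maximum over taxa of the sum of squared differences between that
#' taxon's empirical state frequencies and the global frequencies.
#'
#' @param aln an `rs_alignment`.
#' @export
max_composition_deviation <- function(aln) {
  f <- empirical_frequencies(aln)
  ft <- empirical_frequencies(aln, per_taxon = TRUE)
  max(rowSums((ft - matrix(f, nrow(ft), length(f), byrow = TRUE))^2))
}

#' Per-taxon compositional chi-squared test
#'
#' Expected counts come from the pooled frequencies of all taxa (including
#' the tested one); df = number of states with positive pooled frequency
#' minus one; no continuity correction.  A taxon fails when its upper-tail
#' p-value is below `threshold`.
#'
#' @param aln an `rs_alignment` with at least two taxa.
#' @param threshold failure threshold on the p-value (default 0.05; the
#'   concatenated-dataset taxon-removal screen conventionally uses 0.10).
#' @return an `rs_composition` list: `table` (taxon, chi2, df, p, fail),
#'   `global_freq`, `taxon_freq`, `max_sq_deviation`, `threshold`.
#' @export
composition_chisq <- function(aln, threshold = 0.05) {
  if (n_taxa(aln) < 2) stop("need at least 2 taxa")
  states <- alphabet_states(aln$alphabet)
  cnt <- t(apply(aln$mat, 1, function(r)
    tabulate(match(r, states), nbins = length(states))))
  nt <- rowSums(cnt)
  if (any(nt == 0))
    stop("taxon with zero residues: ", taxa_names(aln)[nt == 0][1])
  f <- colSums(cnt) / sum(cnt)
  sup <- f > 0
  df <- sum(sup) - 1L
  chi2 <- vapply(seq_len(nrow(cnt)), function(i) {
    e <- nt[i] * f[sup]
    sum((cnt[i, sup] - e)^2 / e)
  }, 0)
  p <- pchisq(chi2, df, lower.tail = FALSE)
  ft <- cnt / nt
  dimnames(ft) <- list(taxa_names(aln), states)
  structure(list(
    table = data.frame(taxon = taxa_names(aln), chi2 = chi2, df = df, p = p,
                       fail = p < threshold, stringsAsFactors = FALSE),
    global_freq = setNames(f, states),
    taxon_freq = ft,
    max_sq_deviation = max(rowSums((ft - matrix(f, nrow(ft), length(f),
                                                byrow = TRUE))^2)),
    threshold = threshold), class = "rs_composition")
}

#' @export
print.rs_composition <- function(x, ...) {
  cat(sprintf("compositional chi-squared report: %d taxa, %d fail at p < %g\n",
              nrow(x$table), sum(x$table$fail), x$threshold))
  cat(sprintf("MAX statistic: %.6g\n", x$max_sq_deviation))
  invisible(x)
}

#' Export a composition report as TSV
#'
#' @param report an `rs_composition` object.
#' @param path output file.
#' @export
write_composition_tsv <- function(report, path) {
  write.table(report$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Compress an alignment into unique column patterns
#'
#' @param aln an `rs_alignment`.
#' @return list with `patterns` (integer matrix, taxa x patterns, 0-based,
#'   -1 missing), `weights` (pattern multiplicities summing to `n_sites`),
#'   and `index` (per-site pattern index).
#' @export
pattern_compress <- function(aln) {
  m <- alignment_states_int(aln)
  key <- apply(m, 2, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(patterns = m[, first, drop = FALSE],
       weights = as.vector(table(factor(idx, levels = seq_len(sum(first))))),
       index = idx)
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
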