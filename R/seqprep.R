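# Sequence utilities: degenerate-primer handling, CDS translation, and
# construction of the processing context (mature core + downstream
# extension) from a precursor.

.check_primer <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("primer must be a non-empty string", call. = FALSE)
  seq <- toupper(gsub("[ \t]", "", seq))
  seq <- chartr("U", "T", seq)  # U accepted, normalized to T
  nt <- strsplit(seq, "")[[1]]
  bad <- which(!nt %in% names(.IUPAC_NT))
  if (length(bad))
    stop(sprintf("invalid IUPAC nucleotide '%s' at position %d",
                 nt[bad[1]], bad[1]), call. = FALSE)
  nt
}

#' Degeneracy count of an IUPAC primer
#'
#' Number of concrete sequences encoded by a degenerate primer, i.e. the
#' product of per-position ambiguity-code cardinalities, computed without
#' materializing the expansion.
#'
#' @param primer string over the IUPAC nucleotide alphabet
#'   (`ACGTURYSWKMBDHVN`); `U` is normalized to `T`.
#' @return Expansion size as a double (may exceed integer range).
#' @examples
#' degeneracy_count("TNGGNMGNCARACNATGGARG")  # 2048
#' @export
degeneracy_count <- function(primer) {
  nt <- .check_primer(primer)
  prod(vapply(.IUPAC_NT[nt], length, 0L))
}

#' Expand a degenerate primer into all concrete sequences
#'
#' @inheritParams degeneracy_count
#' @param max_expansion refuse to expand primers encoding more than this
#'   many concrete sequences (default 1e6).
#' @return Character vector of all plain `ACGT` sequences consistent with
#'   the IUPAC codes.
#' @examples
#' expand_degenerate("AR")  # "AA" "AG"
#' @export
expand_degenerate <- function(primer, max_expansion = 1e6) {
  nt <- .check_primer(primer)
  n <- prod(vapply(.IUPAC_NT[nt], length, 0L))
  if (n > max_expansion)
    stop(sprintf("expansion size %.0f exceeds cap %.0f", n, max_expansion),
         call. = FALSE)
  grid <- expand.grid(.IUPAC_NT[nt], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  sort(do.call(paste0, grid))
}

#' Translate a coding nucleotide sequence
#'
#' Standard-genetic-code translation of `nt_seq` in the given frame, up to
#' (not including) the first stop codon.
#'
#' @param nt_seq nucleotide string over `ACGT` (`U` normalized to `T`);
#'   ambiguity codes are rejected.
#' @param frame 0, 1 or 2: number of 5' bases skipped before the first
#'   codon.
#' @return List with `peptide` (amino-acid string) and `stop_found`
#'   (logical).
#' @examples
#' translate_cds("ATGGGA")    # list(peptide = "MG", stop_found = FALSE)
#' translate_cds("ATGTAA")    # list(peptide = "M",  stop_found = TRUE)
#' @export
translate_cds <- function(nt_seq, frame = 0L) {
  if (!is.character(nt_seq) || length(nt_seq) != 1L)
    stop("nt_seq must be a single string", call. = FALSE)
  frame <- as.integer(frame)
  if (is.na(frame) || !frame %in% 0:2)
    stop("frame must be 0, 1 or 2", call. = FALSE)
  seq <- chartr("U", "T", toupper(nt_seq))
  nt <- strsplit(seq, "")[[1]]
  bad <- which(!nt %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("non-ACGT character '%s' at position %d (degenerate %s",
                 nt[bad[1]], bad[1], "sequences cannot be translated)"),
         call. = FALSE)
  nt <- nt[seq_along(nt) > frame]
  if (length(nt) < 3L)
    stop("fewer than one full codon in the chosen frame", call. = FALSE)
  ncodon <- length(nt) %/% 3L
  codons <- vapply(seq_len(ncodon), function(i)
    paste0(nt[(3L * i - 2L):(3L * i)], collapse = ""), "")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    list(peptide = paste0(aa[seq_len(stop_at[1] - 1L)], collapse = ""),
         stop_found = TRUE)
  } else {
    list(peptide = paste0(aa, collapse = ""), stop_found = FALSE)
  }
}

#' Processing context of a prohormone
#'
#' The mature-peptide core together with the precursor residues
#' immediately downstream (needed to decide glycine-donor amidation and
#' C-terminally extended forms) and the acyl-site index.
#'
#' @param core amino-acid string of the cDNA-deduced mature peptide.
#' @param extension amino-acid string of the residues immediately
#'   downstream of the core in the precursor (length >= 1).
#' @param acyl_site 1-based index of the acyl-modified residue
#'   (default 3, the canonical ghrelin serine).
#' @param allow_nonhydroxyl allow an acyl site that is not Ser/Thr.
#' @return An object of class `processing_context`.
#' @examples
#' processing_context("GSSFLSPSHKPPNKGKPPRA", "G")
#' @export
processing_context <- function(core, extension, acyl_site = 3L,
                               allow_nonhydroxyl = FALSE) {
  .check_residues(core)
  if (!is.character(extension) || length(extension) != 1L ||
      !nzchar(extension))
    stop("extension must contain at least one residue", call. = FALSE)
  .check_residues(extension)
  acyl_site <- as.integer(acyl_site)
  if (is.na(acyl_site) || acyl_site < 1L || acyl_site > nchar(core))
    stop("acyl_site must index a core residue", call. = FALSE)
  res <- substr(core, acyl_site, acyl_site)
  if (!res %in% c("S", "T") && !allow_nonhydroxyl)
    stop(sprintf(
      "acyl-site residue '%s' is not hydroxyl-bearing (S/T); %s",
      res, "set allow_nonhydroxyl = TRUE to override"), call. = FALSE)
  structure(list(core = core, extension = extension,
                 acyl_site = acyl_site),
            class = "processing_context")
}

#' @export
print.processing_context <- function(x, ...) {
  cat("<processing_context>\n",
      " core      : ", x$core, " (", nchar(x$core), " aa)\n",
      " extension : ", x$extension, "\n",
      " acyl site : ", x$acyl_site, " (",
      substr(x$core, x$acyl_site, x$acyl_site), ")\n", sep = "")
  invisible(x)
}

#' Extract a processing context from a precursor sequence
#'
#' Slices the mature core and its downstream extension out of a precursor
#' (prepro-peptide) sequence. Indices are 1-based.
#'
#' @param precursor precursor amino-acid string.
#' @param core_start 1-based start of the mature core.
#' @param core_length length of the mature core in residues.
#' @param extension_length number of downstream residues to retain
#'   (>= 1; the glycine-donor rule needs at least one).
#' @param acyl_site acyl-site index within the core (default 3).
#' @param allow_nonhydroxyl passed to [processing_context()].
#' @return A [processing_context()].
#' @examples
#' locate_mature("MAAGSSFLSPSHKPPNKGKPPRAGRR", 4, 20, 3)
#' @export
locate_mature <- function(precursor, core_start, core_length,
                          extension_length, acyl_site = 3L,
                          allow_nonhydroxyl = FALSE) {
  .check_residues(precursor)
  core_start <- as.integer(core_start)
  core_length <- as.integer(core_length)
  extension_length <- as.integer(extension_length)
  if (extension_length < 1L)
    stop("extension_length must be >= 1 (amidation logic needs the ",
         "downstream residue)", call. = FALSE)
  end_core <- core_start + core_length - 1L
  end_ext <- end_core + extension_length
  if (core_start < 1L || end_ext > nchar(precursor))
    stop("core/extension window out of precursor range", call. = FALSE)
  processing_context(substr(precursor, core_start, end_core),
                     substr(precursor, end_core + 1L, end_ext),
                     acyl_site, allow_nonhydroxyl)
}

#' Barfin flounder ghrelin processing context
#'
#' The cDNA-deduced 20-residue mature barfin flounder ghrelin
#' (GSSFLSPSHKPPNKGKPPRA) with its downstream precursor glycine (the
#' amidation donor) and the canonical Ser3 acyl site.
#'
#' @return A [processing_context()].
#' @export
flounder_ghrelin_context <- function() {
  processing_context("GSSFLSPSHKPPNKGKPPRA", "G", acyl_site = 3L)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over Biostrings for single- or multi-record nucleotide or
#' amino-acid FASTA; description lines are preserved as names.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}
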