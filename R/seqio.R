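# Reading and validating aligned protein FASTA and per-cluster Newick trees,
# plus mapping alignment columns to a reference (human FOXP2-style) numbering.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
ALN_ALPHABET <- c(AA_ALPHABET, "-", "X")

#' Construct a validated amino-acid alignment
#'
#' An `aa_alignment` holds aligned protein sequences over the 20 standard
#' amino acids plus the gap character `-` and the ambiguity code `X`.
#' Lowercase residues are uppercased on construction; all sequences must have
#' identical length and unique ids.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned residue strings, same length as
#'   `ids`.
#' @return An object of class `aa_alignment`: a list with elements `ids`,
#'   `seqs` (uppercased residue strings named by id), `mat` (character matrix,
#'   one row per sequence) and `n_columns`.
#' @examples
#' aln <- aa_alignment(c("a", "b"), c("MKV", "M-V"))
#' aln$n_columns
#' @export
aa_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length", call. = FALSE)
  }
  if (length(ids) < 1L) stop("alignment must contain at least one sequence", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
         "); input must be an alignment", call. = FALSE)
  }
  n_columns <- lens[1L]
  if (n_columns < 1L) stop("alignment has zero columns", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad) > 0L) {
    stop("illegal residue character(s): ", paste(bad, collapse = ", "),
         " (allowed: 20 amino acids, '-', 'X')", call. = FALSE)
  }
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, mat = mat, n_columns = n_columns),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment:", length(x$ids), "sequences x",
      x$n_columns, "columns\n")
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @return An [aa_alignment()] object.
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  aa_alignment(names(set), as.character(set))
}

#' Write an alignment to FASTA
#'
#' @param aln An [aa_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  set <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Map alignment columns to reference site numbers
#'
#' Numbers every alignment column after a chosen reference sequence, the way
#' sites are conventionally reported relative to human FOXP2: columns where
#' the reference has a residue get consecutive integer site numbers starting
#' at 1 (the initiator methionine of an untruncated reference is site 1);
#' columns where the reference has a gap get insertion labels of the form
#' `"<previous site>+<offset>"` (`"0+1"` for insertions before the first
#' reference residue), so that downstream per-column results keep a stable,
#' reference-anchored key.
#'
#' @param aln An [aa_alignment()].
#' @param ref_id Id of the reference sequence within `aln`.
#' @return An object of class `reference_map`: list with `labels` (character
#'   vector of length `n_columns`), `sites` (integer site number per column,
#'   `NA` on insertion columns) and `ref_id`.
#' @examples
#' aln <- aa_alignment(c("hs", "ol"), c("M-K", "MQK"))
#' map_reference_numbering(aln, "hs")$labels  # "1" "1+1" "2"
#' @export
map_reference_numbering <- function(aln, ref_id) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!ref_id %in% aln$ids) {
    stop("reference id '", ref_id, "' not present in alignment", call. = FALSE)
  }
  ref <- aln$mat[ref_id, ]
  is_res <- ref != "-"
  sites <- integer(length(ref))
  sites[is_res] <- seq_len(sum(is_res))
  labels <- character(length(ref))
  labels[is_res] <- as.character(sites[is_res])
  prev <- cumsum(is_res)            # site number of last reference residue seen
  off <- seq_along(ref) - findlast_true(is_res)  # offset within insertion run
  labels[!is_res] <- paste0(prev[!is_res], "+", off[!is_res])
  sites[!is_res] <- NA_integer_
  structure(list(labels = labels, sites = sites, ref_id = ref_id),
            class = "reference_map")
}

# index of the most recent TRUE at or before each position (0 if none)
findlast_true <- function(x) {
  idx <- ifelse(x, seq_along(x), 0L)
  cummax(idx)
}

#' Read a cluster subtree in Newick format
#'
#' Cluster topologies drive the per-site parsimony substitution counts, so
#' the tree must be strictly binary: polytomies are rejected rather than
#' silently resolved (an arbitrary resolution would change Fitch counts
#' invisibly).
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object validated to be binary, with
#'   unique leaf labels.
#' @export
read_cluster_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick file: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("cannot parse Newick file: ", path, call. = FALSE)
  validate_cluster_tree(tree)
}

#' Validate a phylo object as a cluster tree
#'
#' @param tree An `ape` `phylo` object.
#' @return The tree, invisibly unchanged, if valid.
#' @export
validate_cluster_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf names in tree", call. = FALSE)
  }
  # every internal node must have exactly two children
  tab <- tabulate(tree$edge[, 1L], nbins = max(tree$edge))
  internal <- sort(unique(tree$edge[, 1L]))
  if (any(tab[internal] != 2L)) {
    stop("tree contains a polytomy; cluster trees must be strictly binary ",
         "(resolve the topology explicitly before use)", call. = FALSE)
  }
  tree
}
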