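# Normalized Kyte-Doolittle hydropathy profiles: the structural
# representation used for clustering and discriminant analysis.

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy constants on the original scale, ranging from
#' -4.5 (arginine, most hydrophilic) to +4.5 (isoleucine, most hydrophobic).
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Normalize a raw Kyte-Doolittle hydropathy value to the unit interval
#'
#' Linear map of the scale's fixed global range \[-4.5, 4.5\] onto \[0, 1\].
#' Normalizing by the fixed range (rather than a per-dataset min/max) makes
#' 0.5 the neutral-hydropathy midpoint, consistent with the convention that
#' alignment gaps take the value 0.5, and makes profiles comparable across
#' datasets.
#'
#' @param raw Numeric vector of raw hydropathy values in \[-4.5, 4.5\].
#' @return Values in \[0, 1\].
#' @examples
#' normalize_hydropathy(c(-4.5, 0, 4.5))  # 0, 0.5, 1
#' @export
normalize_hydropathy <- function(raw) {
  if (any(!is.finite(raw)) || any(raw < -4.5) || any(raw > 4.5)) {
    stop("raw hydropathy outside the Kyte-Doolittle range [-4.5, 4.5]",
         call. = FALSE)
  }
  (raw + 4.5) / 9
}

#' Build normalized hydropathy profiles from an alignment
#'
#' Each sequence becomes a row of per-column normalized hydropathy values in
#' \[0, 1\]. Gap (`-`) and ambiguous (`X`) positions are set to 0.5, the
#' neutral midpoint. The map is element-wise: a sequence's profile does not
#' depend on the other sequences in the alignment.
#'
#' @param aln An [aa_alignment()].
#' @param ref_map Optional [map_reference_numbering()] result; if supplied,
#'   its labels become the column names of the profile matrix.
#' @param rescale `"scale"` (default) normalizes by the Kyte-Doolittle global
#'   range; `"data"` rescales by the min/max of the raw values observed in
#'   this alignment (gaps stay at 0.5).
#' @return Numeric matrix (sequences x columns) with row names from the
#'   alignment ids, class `profile_matrix`.
#' @examples
#' aln <- aa_alignment(c("a", "b"), c("MK-", "MIV"))
#' build_profiles(aln)
#' @export
build_profiles <- function(aln, ref_map = NULL, rescale = c("scale", "data")) {
  stopifnot(inherits(aln, "aa_alignment"))
  rescale <- match.arg(rescale)
  raw <- kyte_doolittle[aln$mat]        # NA where '-' or 'X'
  dim(raw) <- dim(aln$mat)
  if (rescale == "scale") {
    vals <- (raw + 4.5) / 9
  } else if (all(is.na(raw))) {
    vals <- array(0.5, dim = dim(raw))
  } else {
    rng <- range(raw, na.rm = TRUE)
    if (diff(rng) == 0) {
      vals <- array(0.5, dim = dim(raw))
    } else {
      vals <- (raw - rng[1L]) / diff(rng)
    }
  }
  vals[is.na(raw)] <- 0.5
  rownames(vals) <- aln$ids
  colnames(vals) <- if (!is.null(ref_map)) ref_map$labels else as.character(seq_len(aln$n_columns))
  structure(vals, class = c("profile_matrix", class(vals)))
}
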