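# Configuration-space bookkeeping: the exhaustive rotamer-combination
# count of a patch and the (much smaller) number of chi1 configurations
# actually visited by the stratified SCMF filter.

#' Count the conformational spaces of a patch
#'
#' The exhaustive count is the product of per-residue rotamer counts. The
#' chi1-configuration count multiplies, per residue: the number of
#' non-empty chi1 bins (standard types), the rotamer count (histidine,
#' sampled exhaustively), or 1 (serine/cysteine, left free for the SCMF).
#' Counts are exact in double precision up to 2^53 (~9e15), far beyond any
#' 9-residue patch.
#'
#' @param rotamer_sets per-residue rotamer sets (e.g.
#'   `multicopy_system$rotamer_sets`), or a bare numeric vector of
#'   per-residue rotamer counts (then only the exhaustive count is
#'   defined).
#' @return list (`space_size`): `exhaustive_count`, `chi1_config_count`,
#'   `per_residue_rotamers`, `per_residue_factors`.
#' @export
count_spaces <- function(rotamer_sets) {
  if (is.numeric(rotamer_sets)) {
    return(structure(list(exhaustive_count = prod(rotamer_sets),
                          chi1_config_count = NA_real_,
                          per_residue_rotamers = rotamer_sets,
                          per_residue_factors = NA), class = "space_size"))
  }
  nrot <- vapply(rotamer_sets, function(rs) length(rs$chis), numeric(1))
  factors <- vapply(rotamer_sets, function(rs) {
    if (length(rs$chis) == 0) stop("residue with zero rotamers")
    if (rs$res_type == "HIS") length(rs$chis)
    else if (rs$res_type %in% c("SER", "CYS")) 1
    else length(unique(rs$bins))
  }, numeric(1))
  structure(list(exhaustive_count = prod(nrot),
                 chi1_config_count = prod(factors),
                 per_residue_rotamers = nrot,
                 per_residue_factors = factors), class = "space_size")
}

#' @export
print.space_size <- function(x, ...) {
  cat(sprintf("space_size: exhaustive %s, chi1 configurations %s\n",
              format(x$exhaustive_count, big.mark = ","),
              format(x$chi1_config_count, big.mark = ",")))
  invisible(x)
}
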