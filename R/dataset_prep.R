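# Case cleaning: map bound and unbound structures of the same protein onto
# a consistent residue correspondence (per-chain global sequence
# alignment), then apply the rejection/fixing rules: interface residues
# must match exactly (truncating incomplete side chains consistently),
# non-interface residues are removed or truncated consistently, and a case
# is rejected when more than 5% of a protein's residues are touched.

# identity substitution matrix over amino-acid one-letter codes
identity_submat <- function() {
  letters20 <- c(unname(AA3TO1), "X")
  m <- diag(1, length(letters20))
  dimnames(m) <- list(letters20, letters20)
  m
}

#' Align bound and unbound sequences of one protein
#'
#' Global (Needleman-Wunsch) alignment per chain of the sequences extracted
#' from the ATOM records, identity scoring, gap open 5 / extend 1. Chains
#' are paired by order of appearance. Aligned positions become residue-key
#' pairs (substituted positions are paired but flagged); gaps are recorded
#' as unmatched.
#'
#' @param bound,unbound `pdb_structure` objects of the same protein.
#' @return object of class `case_mapping`: data.frame `pairs` (columns
#'   `bound`, `unbound`, `identical`), plus `unmatched_bound` and
#'   `unmatched_unbound` key vectors.
#' @export
align_case_sequences <- function(bound, unbound) {
  cb <- unique(bound$atoms$chain)
  cu <- unique(unbound$atoms$chain)
  if (length(cb) != length(cu))
    stop("cannot pair chains: bound has [", paste(cb, collapse = ","),
         "], unbound has [", paste(cu, collapse = ","), "]")
  pairs <- data.frame(bound = character(0), unbound = character(0),
                      identical = logical(0), stringsAsFactors = FALSE)
  um_b <- character(0)
  um_u <- character(0)
  subm <- identity_submat()
  for (k in seq_along(cb)) {
    sb <- chain_sequence(bound, cb[k])
    su <- chain_sequence(unbound, cu[k])
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sb$seq), Biostrings::AAString(su$seq),
      substitutionMatrix = subm, gapOpening = 5, gapExtension = 1,
      type = "global")
    ab <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    au <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ib <- 0L
    iu <- 0L
    for (i in seq_along(ab)) {
      if (ab[i] != "-") ib <- ib + 1L
      if (au[i] != "-") iu <- iu + 1L
      if (ab[i] != "-" && au[i] != "-") {
        pairs <- rbind(pairs, data.frame(
          bound = sb$reskeys[ib], unbound = su$reskeys[iu],
          identical = ab[i] == au[i], stringsAsFactors = FALSE))
      } else if (ab[i] != "-") um_b <- c(um_b, sb$reskeys[ib])
      else um_u <- c(um_u, su$reskeys[iu])
    }
  }
  structure(list(pairs = pairs, unmatched_bound = um_b,
                 unmatched_unbound = um_u), class = "case_mapping")
}

#' @export
print.case_mapping <- function(x, ...) {
  cat(sprintf("case_mapping: %d pairs (%d identical), %d/%d unmatched bound/unbound\n",
              nrow(x$pairs), sum(x$pairs$identical),
              length(x$unmatched_bound), length(x$unmatched_unbound)))
  invisible(x)
}

# fix one protein pair (bound, unbound, its mapping) given its interface
# keys; returns updated structures + bookkeeping or a rejection reason
clean_one_protein <- function(bound, unbound, mapping, interface) {
  rtb <- residue_table(bound)
  rtu <- residue_table(unbound)
  pairs <- mapping$pairs
  # rule 1: interface must be fully and identically present in unbound
  if (any(interface %in% mapping$unmatched_bound) ||
      any(interface %in% pairs$bound[!pairs$identical]))
    return(list(rejection = "missing interface residue in unbound"))
  iface_pairs <- pairs[pairs$bound %in% interface, ]
  # "additional" unbound residues inside the interface span: unmatched
  # unbound residues falling between mapped interface neighbours
  if (length(mapping$unmatched_unbound)) {
    span <- match(iface_pairs$unbound, rtu$reskey)
    extra <- match(mapping$unmatched_unbound, rtu$reskey)
    if (any(extra > min(span) & extra < max(span)))
      return(list(rejection = "additional interface residue in unbound"))
  }
  n_touched <- 0L
  # rule 2: interface residues with incomplete side chains are truncated
  # consistently; missing backbone atoms reject the case
  for (i in seq_len(nrow(iface_pairs))) {
    kb <- iface_pairs$bound[i]
    ku <- iface_pairs$unbound[i]
    bb_ok <- rtb$backbone_complete[rtb$reskey == kb] &&
      rtu$backbone_complete[rtu$reskey == ku]
    if (!bb_ok)
      return(list(rejection = "missing backbone atom in interface residue"))
    sc_ok <- rtb$sidechain_complete[rtb$reskey == kb] &&
      rtu$sidechain_complete[rtu$reskey == ku]
    if (!sc_ok) {
      tb <- truncate_residue(get_residue(bound, kb))
      tu <- truncate_residue(get_residue(unbound, ku))
      # consistent truncation: same resulting type on both sides
      if (tb$resid[1] != tu$resid[1]) {
        keep <- intersect(c("N", "CA", "C", "O"), intersect(tb$elety,
                                                            tu$elety))
        tb <- tb[tb$elety %in% keep, ]
        tb$resid <- "GLY"
        tu <- tu[tu$elety %in% keep, ]
        tu$resid <- "GLY"
      }
      bound <- replace_residue(bound, kb, tb)
      unbound <- replace_residue(unbound, ku, tu)
      n_touched <- n_touched + 1L
    }
  }
  # rule 4: non-interface region — remove unilateral or backbone-incomplete
  # residues, truncate incomplete side chains consistently
  non_iface_pairs <- pairs[!(pairs$bound %in% interface), ]
  drop_b <- character(0)
  drop_u <- character(0)
  for (i in seq_len(nrow(non_iface_pairs))) {
    kb <- non_iface_pairs$bound[i]
    ku <- non_iface_pairs$unbound[i]
    bb_ok <- rtb$backbone_complete[rtb$reskey == kb] &&
      rtu$backbone_complete[rtu$reskey == ku]
    if (!bb_ok || !non_iface_pairs$identical[i]) {
      drop_b <- c(drop_b, kb)
      drop_u <- c(drop_u, ku)
      n_touched <- n_touched + 1L
      next
    }
    sc_ok <- rtb$sidechain_complete[rtb$reskey == kb] &&
      rtu$sidechain_complete[rtu$reskey == ku]
    if (!sc_ok) {
      tb <- truncate_residue(get_residue(bound, kb))
      tu <- truncate_residue(get_residue(unbound, ku))
      if (tb$resid[1] != tu$resid[1]) {
        keep <- intersect(tb$elety, tu$elety)
        tb <- tb[tb$elety %in% keep, ]
        tb$resid <- "GLY"
        tu <- tu[tu$elety %in% keep, ]
        tu$resid <- "GLY"
      }
      bound <- replace_residue(bound, kb, tb)
      unbound <- replace_residue(unbound, ku, tu)
      n_touched <- n_touched + 1L
    }
  }
  drop_b <- c(drop_b, mapping$unmatched_bound)
  drop_u <- c(drop_u, mapping$unmatched_unbound)
  n_touched <- n_touched + length(mapping$unmatched_bound) +
    length(mapping$unmatched_unbound)
  if (length(drop_b))
    bound <- subset_structure(bound, setdiff(residue_table(bound)$reskey,
                                             drop_b))
  if (length(drop_u))
    unbound <- subset_structure(unbound,
                                setdiff(residue_table(unbound)$reskey,
                                        drop_u))
  frac <- n_touched / max(nrow(rtb), nrow(rtu))
  if (frac > 0.05)
    return(list(rejection = sprintf(
      "more than 5%% of residues removed or truncated (%.1f%%)",
      100 * frac)))
  mapping$pairs <- mapping$pairs[!(mapping$pairs$bound %in% drop_b), ]
  list(rejection = NULL, bound = bound, unbound = unbound,
       mapping = mapping, removed_fraction = frac)
}

#' Clean a docking case (bound/unbound receptor and ligand)
#'
#' Applies the case-cleaning procedure: per-chain sequence alignment, the
#' interface-presence rejection rule, consistent truncation of incomplete
#' interface side chains (missing backbone rejects), removal/truncation in
#' the non-interface region with the 5% rejection threshold (per protein).
#' Backbone O atoms missing from otherwise complete backbones are repaired
#' by ideal-geometry placement first.
#'
#' @param bound_receptor,unbound_receptor,bound_ligand,unbound_ligand
#'   `pdb_structure` objects.
#' @param interface_cutoff interface distance cutoff in Angstrom.
#' @return object of class `clean_case`: cleaned structures, two
#'   `case_mapping`s, interface key sets, `rejection` (NULL or reason) and
#'   `removed_fraction` per protein.
#' @export
clean_case <- function(bound_receptor, unbound_receptor, bound_ligand,
                       unbound_ligand, interface_cutoff = 6) {
  bound_receptor <- repair_backbone_o(bound_receptor)
  unbound_receptor <- repair_backbone_o(unbound_receptor)
  bound_ligand <- repair_backbone_o(bound_ligand)
  unbound_ligand <- repair_backbone_o(unbound_ligand)
  iface_r <- interface_residues(bound_receptor, bound_ligand,
                                interface_cutoff)
  iface_l <- interface_residues(bound_ligand, bound_receptor,
                                interface_cutoff)
  map_r <- align_case_sequences(bound_receptor, unbound_receptor)
  map_l <- align_case_sequences(bound_ligand, unbound_ligand)
  res_r <- clean_one_protein(bound_receptor, unbound_receptor, map_r,
                             iface_r)
  if (!is.null(res_r$rejection))
    return(structure(list(rejection = paste("receptor:", res_r$rejection)),
                     class = "clean_case"))
  res_l <- clean_one_protein(bound_ligand, unbound_ligand, map_l, iface_l)
  if (!is.null(res_l$rejection))
    return(structure(list(rejection = paste("ligand:", res_l$rejection)),
                     class = "clean_case"))
  structure(list(
    bound_receptor = res_r$bound, unbound_receptor = res_r$unbound,
    bound_ligand = res_l$bound, unbound_ligand = res_l$unbound,
    mapping_receptor = res_r$mapping, mapping_ligand = res_l$mapping,
    interface_receptor = iface_r, interface_ligand = iface_l,
    rejection = NULL,
    removed_fraction = c(receptor = res_r$removed_fraction,
                         ligand = res_l$removed_fraction)),
    class = "clean_case")
}

#' @export
print.clean_case <- function(x, ...) {
  if (!is.null(x$rejection)) {
    cat("clean_case: REJECTED -", x$rejection, "\n")
  } else {
    cat(sprintf("clean_case: accepted; interface %d+%d residues; removed fraction %.3f/%.3f\n",
                length(x$interface_receptor), length(x$interface_ligand),
                x$removed_fraction[1], x$removed_fraction[2]))
  }
  invisible(x)
}
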