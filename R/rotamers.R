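# Rotamer library handling and side-chain construction. A rotamer is a
# tuple of chi torsion angles for a residue type; side chains are built on
# the fixed (unbound) backbone from internal coordinates. The library is
# supplemented per residue with the unbound conformation when no library
# rotamer comes within 0.6 A RMSD of it.

CANONICAL_CHI1 <- c("g+" = 60, "t" = 180, "g-" = -60)

#' Assign a chi1 angle to its canonical bin
#'
#' The three canonical chi1 wells are g+ (60 deg), t (180 deg) and g-
#' (-60 deg); the nearest well by circular distance is returned, boundary
#' ties broken in the order g+, t, g-.
#'
#' @param angle chi1 angle(s) in degrees.
#' @return character vector of bin labels ("g+", "t", "g-").
#' @export
chi1_bin <- function(angle) {
  vapply(angle, function(a) {
    d <- abs(wrap_angle(a - CANONICAL_CHI1))
    names(CANONICAL_CHI1)[which.min(d)]
  }, character(1))
}

new_rotamer_set <- function(res_type, chis, source) {
  # chis: list of numeric vectors (full length n_chi(res_type))
  k <- n_chi(res_type)
  stopifnot(all(lengths(chis) == k))
  bins <- if (k >= 1) chi1_bin(vapply(chis, `[`, numeric(1), 1))
          else rep(NA_character_, length(chis))
  list(res_type = res_type, chis = chis, source = source, bins = bins)
}

# extend a chi tuple with the defaulted terminal torsions (LYS chi4,
# ARG chi4/chi5); errors if the count cannot be reconciled
complete_chis <- function(res_type, chis) {
  k <- n_chi(res_type)
  defs <- CHI_DEFAULTS[[res_type]]
  if (length(chis) == k) return(as.numeric(chis))
  if (!is.null(defs) && length(chis) == k - length(defs))
    return(as.numeric(c(chis, defs)))
  if (!is.null(defs) && length(chis) > k - length(defs) &&
      length(chis) < k)
    return(as.numeric(c(chis, defs[seq(length(chis) - (k - length(defs)) + 1,
                                       length(defs))])))
  stop(sprintf("%s expects %d chi angles (got %d)", res_type, k,
               length(chis)))
}

#' Load a rotamer library from a whitespace-delimited text file
#'
#' Each row is `RES chi1 [chi2 [chi3 [chi4 [chi5]]]]`; `#` starts a
#' comment. Missing terminal torsions for LYS (chi4) and ARG (chi4, chi5)
#' are filled with their defaults (180 and 180/0); the atoms those defaults
#' place are excluded from energy calculations elsewhere. Duplicate chi
#' tuples within a type are dropped with a warning.
#'
#' @param path path to the library file.
#' @return object of class `rotamer_library`: per flexible residue type a
#'   rotamer set (chi tuples, chi1 bins, source tags).
#' @export
load_rotamer_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  lines <- trimws(sub("#.*$", "", raw))
  keep <- which(nzchar(lines))
  entries <- list()
  for (i in keep) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    rt <- toupper(tok[1])
    if (!(rt %in% FLEXIBLE_TYPES))
      stop(sprintf("line %d: unknown or inflexible residue type '%s'",
                   i, tok[1]))
    ang <- suppressWarnings(as.numeric(tok[-1]))
    if (!length(ang) || anyNA(ang))
      stop(sprintf("line %d: malformed rotamer row", i))
    chis <- wrap_angle(complete_chis(rt, ang))
    entries[[rt]] <- c(entries[[rt]], list(chis))
  }
  types <- list()
  for (rt in names(entries)) {
    sig <- vapply(entries[[rt]], function(ch)
      paste(sprintf("%.4f", ch), collapse = ","), character(1))
    if (anyDuplicated(sig)) {
      warning(sprintf("%s: %d duplicate rotamer(s) dropped", rt,
                      sum(duplicated(sig))))
      entries[[rt]] <- entries[[rt]][!duplicated(sig)]
    }
    types[[rt]] <- new_rotamer_set(rt, entries[[rt]],
                                   rep("library", length(entries[[rt]])))
  }
  structure(list(types = types, provenance = path),
            class = "rotamer_library")
}

#' The shipped backbone-independent default rotamer library
#'
#' An idealized canonical-bin library (chi angles on the classical g+/t/g-
#' wells, aromatic chi2 on +/-90): a synthetic stand-in for statistical
#' libraries, adequate for pipeline use and fully determined by the code.
#'
#' @return a `rotamer_library`.
#' @export
default_rotamer_library <- function() {
  path <- system.file("extdata", "rotamers_default.txt",
                      package = "patchsampler")
  lib <- load_rotamer_library(path)
  lib$provenance <- "patchsampler default (idealized canonical bins)"
  lib
}

#' @export
print.rotamer_library <- function(x, ...) {
  n <- vapply(x$types, function(t) length(t$chis), integer(1))
  cat(sprintf("rotamer_library: %d types, %d rotamers (%s)\n",
              length(n), sum(n), x$provenance))
  invisible(x)
}

#' Build side-chain heavy atoms from chi angles
#'
#' Sequential internal-coordinate construction (ideal bond lengths and
#' angles from the united-atom tables) anchored on the residue backbone.
#'
#' @param backbone 3 x 3 (or more) coordinate matrix with rownames
#'   containing N, CA, C — e.g. from [residue_coords()] — or a residue atom
#'   data.frame.
#' @param res_type 3-letter code of a flexible residue type.
#' @param chis chi angles in degrees; terminal LYS/ARG torsions may be
#'   omitted (defaults applied).
#' @return coordinate matrix of the side-chain atoms (rownames = atom
#'   names, in build order, starting at CB).
#' @export
build_side_chain <- function(backbone, res_type, chis) {
  if (is.data.frame(backbone))
    backbone <- residue_coords(backbone,
                               intersect(c("N", "CA", "C", "O"),
                                         backbone$elety))
  if (!all(c("N", "CA", "C") %in% rownames(backbone)))
    stop("backbone must contain N, CA and C")
  if (res_type %in% c("ALA", "GLY") || is.null(sidechain_topology[[res_type]]))
    stop("not a flexible residue type: ", res_type)
  place_topology(backbone, res_type, complete_chis(res_type, chis))
}

# topology walk shared by flexible and fixed (ALA) side-chain building
place_topology <- function(backbone, res_type, chis = numeric(0)) {
  tp <- sidechain_topology[[res_type]]
  if (is.null(tp)) return(matrix(numeric(0), 0, 3))
  pos <- list(N = backbone["N", ], CA = backbone["CA", ],
              C = backbone["C", ])
  out <- matrix(NA_real_, nrow(tp), 3, dimnames = list(tp$atom, NULL))
  for (i in seq_len(nrow(tp))) {
    tors <- if (tp$tors_type[i] == "chi")
      chis[tp$chi_index[i]] + tp$offset[i] else tp$offset[i]
    p <- place_atom(pos[[tp$a[i]]], pos[[tp$b[i]]], pos[[tp$c[i]]],
                    tp$len[i], tp$ang[i], tors)
    pos[[tp$atom[i]]] <- p
    out[i, ] <- p
  }
  out
}

#' Measure the chi torsion angles of a residue
#'
#' @param res a residue atom data.frame (from [get_residue()]) or a
#'   coordinate matrix with atom-name rownames covering backbone and side
#'   chain.
#' @return numeric vector of chi angles in degrees, (-180, 180]; length
#'   [n_chi()] of the type.
#' @export
measure_chis <- function(res, res_type = NULL) {
  if (is.data.frame(res)) {
    if (is.null(res_type)) res_type <- res$resid[1]
    coords <- residue_coords(res, res$elety)
  } else {
    coords <- res
    if (is.null(res_type)) stop("res_type required for a coordinate matrix")
  }
  defs <- chi_definitions[[res_type]]
  if (is.null(defs)) return(numeric(0))
  vapply(defs, function(quad) {
    if (!all(quad %in% rownames(coords)))
      stop("incomplete side chain: missing ",
           paste(setdiff(quad, rownames(coords)), collapse = ","))
    dihedral_angle(coords[quad[1], ], coords[quad[2], ],
                   coords[quad[3], ], coords[quad[4], ])
  }, numeric(1))
}

# side-chain RMSD (in place, shared backbone) between an observed residue
# side chain and a chi tuple built on the same backbone
rotamer_rmsd_to_residue <- function(res_atoms, res_type, chis) {
  sc_names <- sidechain_atoms(res_type)
  obs <- residue_coords(res_atoms, sc_names)
  built <- build_side_chain(res_atoms, res_type, chis)
  rmsd_coords(built[sc_names, , drop = FALSE], obs)
}

#' Supplement a rotamer set with the unbound conformation
#'
#' Each library rotamer is built on the unbound backbone and compared to
#' the observed unbound side chain by in-place side-chain RMSD; if none is
#' within `threshold` (0.6 A), a rotamer carrying the measured unbound chi
#' angles is appended with source tag "unbound".
#'
#' @param rotamers a per-type rotamer set (element of
#'   `rotamer_library$types`).
#' @param unbound_res atom data.frame of the unbound residue (side chain
#'   complete).
#' @param threshold supplementation RMSD threshold in Angstrom.
#' @return the (possibly extended) rotamer set.
#' @export
supplement_with_unbound <- function(rotamers, unbound_res,
                                    threshold = 0.6) {
  rt <- rotamers$res_type
  stopifnot(unbound_res$resid[1] == rt)
  rmsds <- vapply(rotamers$chis, function(ch)
    rotamer_rmsd_to_residue(unbound_res, rt, ch), numeric(1))
  if (length(rmsds) && min(rmsds) <= threshold) return(rotamers)
  chis_u <- measure_chis(unbound_res, rt)
  new_rotamer_set(rt, c(rotamers$chis, list(as.numeric(chis_u))),
                  c(rotamers$source, "unbound"))
}

# per-residue supplemented rotamer set with prebuilt coordinates on the
# residue's own (unbound) backbone; the workhorse object for SCMF
residue_rotamers <- function(unbound_res, lib, threshold = 0.6) {
  rt <- unbound_res$resid[1]
  set <- lib$types[[rt]]
  if (is.null(set)) stop("no rotamers for type ", rt)
  set <- supplement_with_unbound(set, unbound_res, threshold)
  set$coords <- lapply(set$chis, function(ch)
    build_side_chain(unbound_res, rt, ch))
  set
}
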