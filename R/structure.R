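# Protein structure model: a light-weight atom-table representation with
# PDB reading/writing and the residue-fixing primitives used by dataset
# cleaning. Heavy atoms only (united-atom model); hydrogens are never kept
# or built.

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `resid`,
#'   `elety` (atom name), `x`, `y`, `z`, `occ`. Rows must be in file order
#'   (atoms of a residue contiguous).
#' @param id structure identifier.
#' @return object of class `pdb_structure`.
#' @export
structure_from_atoms <- function(atoms, id = "struct") {
  stopifnot(all(c("chain", "resno", "icode", "resid", "elety",
                  "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$elem <- atom_element(atoms$elety)
  atoms$reskey <- paste(atoms$chain, atoms$resno, atoms$icode, sep = ".")
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "pdb_structure")
}

#' Read a PDB file
#'
#' Parses ATOM records into a heavy-atom structure. Hydrogens, waters and
#' HETATM groups are dropped (selenomethionine, MSE, is rescued and mapped
#' to MET with SE renamed SD). For alternate locations, the
#' highest-occupancy conformer is kept, ties broken in favour of altloc "A".
#' Residues of non-standard type are dropped with a warning.
#'
#' @param path path to a PDB file.
#' @param id structure id (defaults to the file name).
#' @param model model number to read from multi-model files (default 1).
#' @return a `pdb_structure`.
#' @export
read_pdb <- function(path, id = sub("\\.pdb$", "", basename(path)),
                     model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) >= model) {
    ends <- which(rec == "ENDMDL")
    from <- model_starts[model]
    to <- if (length(ends) >= model) ends[model] else length(lines)
    keep_range <- seq(from, to)
  } else keep_range <- seq_along(lines)
  idx <- keep_range[rec[keep_range] %in% c("ATOM  ", "HETATM")]
  if (!length(idx)) stop("empty structure: no ATOM records in ", path)
  ln <- lines[idx]
  f <- function(a, b) substr(ln, a, b)
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  resno <- suppressWarnings(as.integer(f(23, 26)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resno))
  if (length(bad))
    stop("unparseable ATOM record at line ", idx[bad[1]], " of ", path)
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[!is.finite(occ)] <- 1
  atoms <- data.frame(
    record = rec[idx],
    elety = trimws(f(13, 16)), altloc = trimws(f(17, 17)),
    resid = trimws(f(18, 20)), chain = trimws(f(22, 22)),
    resno = resno, icode = trimws(f(27, 27)),
    x = x, y = y, z = z, occ = occ, stringsAsFactors = FALSE)

  # selenomethionine -> methionine
  mse <- atoms$resid == "MSE"
  atoms$resid[mse] <- "MET"
  atoms$elety[mse & atoms$elety == "SE"] <- "SD"
  atoms$record[mse] <- "ATOM  "

  atoms <- atoms[atoms$record == "ATOM  " & atoms$resid != "HOH", ]
  # drop hydrogens/deuteriums (names like H, 1HB, HG1, D...)
  elem1 <- atom_element(atoms$elety)
  atoms <- atoms[!(elem1 %in% c("H", "D")), ]

  nonstd <- setdiff(unique(atoms$resid), AA3)
  if (length(nonstd)) {
    warning("dropping non-standard residue type(s): ",
            paste(nonstd, collapse = ", "))
    atoms <- atoms[!(atoms$resid %in% nonstd), ]
  }
  if (!nrow(atoms)) stop("empty structure: no usable ATOM records in ", path)

  # altloc resolution: keep the highest-occupancy conformer per atom,
  # ties broken toward altloc "A" (then alphabetically)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
  if (any(nzchar(atoms$altloc))) {
    ord <- order(key, -atoms$occ, atoms$altloc)
    atoms <- atoms[ord, ]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                     atoms$elety)), ]
    # restore file order
    atoms <- atoms[order(as.integer(rownames(atoms))), ]
  }
  atoms$record <- NULL
  atoms$altloc <- NULL
  structure_from_atoms(atoms, id = id)
}

#' Write a structure (or several conformations) as a PDB file
#'
#' @param s a `pdb_structure`, or a list of them; a list is written as
#'   MODEL/ENDMDL blocks sharing numbering.
#' @param path output file path.
#' @param remarks optional character vector written as REMARK lines.
#' @return invisibly, the path.
#' @export
write_pdb <- function(s, path, remarks = NULL) {
  multi <- !inherits(s, "pdb_structure")
  models <- if (multi) s else list(s)
  out <- character(0)
  if (!is.null(remarks)) out <- paste("REMARK   ", remarks)
  for (m in seq_along(models)) {
    a <- models[[m]]$atoms
    if (!nrow(a)) stop("cannot write an empty structure")
    if (any(abs(c(a$x, a$y, a$z)) > 9999.999))
      stop("coordinate exceeds PDB fixed-width field (|x| > 9999.999)")
    name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                    sprintf(" %-3s", a$elety))
    recs <- sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    pmin(seq_len(nrow(a)), 99999L), name4, a$resid,
                    a$chain, a$resno, a$icode, a$x, a$y, a$z, a$occ, 0,
                    a$elem)
    if (multi) recs <- c(sprintf("MODEL     %4d", m), recs, "ENDMDL")
    out <- c(out, recs)
  }
  out <- c(out, "END")
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  writeLines(out, con)
  close(con)
  invisible(path)
}

#' Per-residue summary table of a structure
#'
#' One row per residue, in file order, with completeness flags. A residue is
#' "effective" when its type is neither ALA nor GLY (its side chain is
#' flexible). Backbone completeness requires N, CA and C (O is repairable
#' and not required).
#'
#' @param s a `pdb_structure`.
#' @return data.frame with columns `reskey`, `chain`, `resno`, `icode`,
#'   `resid`, `n_atoms`, `is_effective`, `backbone_complete`,
#'   `sidechain_complete`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  first <- !duplicated(a$reskey)
  keys <- a$reskey[first]
  by_res <- split(a$elety, factor(a$reskey, levels = keys))
  resid <- a$resid[first]
  sc_ok <- mapply(function(rt, nm) all(sidechain_atoms(rt) %in% nm),
                  resid, by_res, USE.NAMES = FALSE)
  data.frame(
    reskey = keys, chain = a$chain[first], resno = a$resno[first],
    icode = a$icode[first], resid = resid,
    n_atoms = lengths(by_res),
    is_effective = !(resid %in% c("ALA", "GLY")),
    backbone_complete = vapply(by_res, function(nm)
      all(c("N", "CA", "C") %in% nm), logical(1), USE.NAMES = FALSE),
    sidechain_complete = sc_ok,
    stringsAsFactors = FALSE)
}

#' Extract the atom rows of one residue
#' @param s a `pdb_structure`.
#' @param reskey residue key "chain.resno.icode".
#' @return data.frame of atoms.
#' @export
get_residue <- function(s, reskey) {
  r <- s$atoms[s$atoms$reskey == reskey, ]
  if (!nrow(r)) stop("no such residue: ", reskey)
  r
}

#' Keep only the given residues of a structure
#' @param s a `pdb_structure`; @param reskeys residue keys to keep.
#' @return a `pdb_structure`.
#' @export
subset_structure <- function(s, reskeys) {
  structure_from_atoms(s$atoms[s$atoms$reskey %in% reskeys,
                               setdiff(names(s$atoms), c("elem", "reskey"))],
                       id = s$id)
}

residue_coords <- function(res_atoms, names) {
  m <- as.matrix(res_atoms[match(names, res_atoms$elety), c("x", "y", "z")])
  if (anyNA(m)) stop("missing atom(s): ",
                     paste(names[!names %in% res_atoms$elety], collapse = ","))
  dimnames(m) <- list(names, NULL)
  m
}

#' Truncate a residue with a missing side chain to ALA or GLY
#'
#' If CA and CB are present the residue becomes an ALA (keeping N, CA, C, O,
#' CB); if CB is absent it becomes a GLY (keeping N, CA, C, O). Idempotent.
#'
#' @param res data.frame of one residue's atoms (as from [get_residue()]).
#' @return the truncated residue atom table with updated `resid`.
#' @export
truncate_residue <- function(res) {
  if (!all(c("N", "CA", "C") %in% res$elety))
    stop("cannot truncate residue with incomplete backbone")
  if ("CB" %in% res$elety) {
    res <- res[res$elety %in% c("N", "CA", "C", "O", "CB"), ]
    res$resid <- "ALA"
  } else {
    res <- res[res$elety %in% c("N", "CA", "C", "O"), ]
    res$resid <- "GLY"
  }
  res
}

# replace the atoms of one residue inside a structure (keeps position)
replace_residue <- function(s, reskey, res_atoms) {
  i <- which(s$atoms$reskey == reskey)
  if (!length(i)) stop("no such residue: ", reskey)
  cols <- setdiff(names(s$atoms), c("elem", "reskey"))
  before <- s$atoms[seq_len(min(i) - 1), cols]
  after <- if (max(i) < nrow(s$atoms))
    s$atoms[seq(max(i) + 1, nrow(s$atoms)), cols] else s$atoms[0, cols]
  structure_from_atoms(rbind(before, res_atoms[, cols], after), id = s$id)
}

# add a backbone O by ideal geometry when missing (terminal or truncated
# records); uses the next residue's N as the in-plane reference if available
repair_backbone_o <- function(s) {
  rt <- residue_table(s)
  need <- rt$reskey[rt$backbone_complete &
                      !vapply(rt$reskey, function(k)
                        "O" %in% s$atoms$elety[s$atoms$reskey == k],
                        logical(1))]
  for (k in need) {
    res <- get_residue(s, k)
    i <- match(k, rt$reskey)
    nn <- NULL
    if (i < nrow(rt) && rt$chain[i + 1] == rt$chain[i]) {
      nxt <- get_residue(s, rt$reskey[i + 1])
      if ("N" %in% nxt$elety)
        nn <- as.numeric(nxt[nxt$elety == "N", c("x", "y", "z")])
    }
    ca <- as.numeric(res[res$elety == "CA", c("x", "y", "z")])
    cc <- as.numeric(res[res$elety == "C", c("x", "y", "z")])
    nh <- as.numeric(res[res$elety == "N", c("x", "y", "z")])
    o <- if (!is.null(nn)) place_atom(nn, ca, cc, 1.231, 120.5, 180)
         else place_atom(nh, ca, cc, 1.231, 120.5, 135)
    orow <- res[1, ]
    orow$elety <- "O"
    orow$x <- o[1]; orow$y <- o[2]; orow$z <- o[3]; orow$occ <- 1
    s <- replace_residue(s, k, rbind(res, orow))
  }
  s
}

#' @export
print.pdb_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("pdb_structure '%s': %d atoms, %d residues, %d chain(s)\n",
              x$id, nrow(x$atoms), nrow(rt), length(unique(rt$chain))))
  invisible(x)
}

# one-letter sequence of a chain (unknown types -> X)
chain_sequence <- function(s, chain) {
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain, ]
  ltr <- AA3TO1[rt$resid]
  ltr[is.na(ltr)] <- "X"
  list(seq = paste(ltr, collapse = ""), reskeys = rt$reskey)
}
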