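# Synthetic fixtures: fully self-contained toy inputs (ideal peptide
# backbones, miniature rotamer libraries, minimal parameter tables,
# bound/unbound patch pairs with a known truth) so every pipeline stage is
# testable without downloading any structure. The toy world: a short
# surface strand of mixed flexible residues with zero backbone change
# between bound and unbound, the bound side chains drawn exactly from the
# toy library, the unbound ones perturbed out of their chi1 bins, and a
# poly-ALA partner strand close enough to trigger interface detection.

#' Miniature rotamer library on canonical chi1 bins
#'
#' Per type, `rotamers_per_type` rotamers cycling through the g+/t/g- chi1
#' wells (all three covered when >= 3) with a small deterministic jitter;
#' higher torsions cycle the canonical wells likewise.
#'
#' @param types flexible residue types to include.
#' @param rotamers_per_type rotamer count per type (1..30).
#' @param seed integer seed for the jitter.
#' @param jitter max absolute torsion jitter in degrees.
#' @return a `rotamer_library`.
#' @export
make_toy_library <- function(types, rotamers_per_type = 3L, seed = 0L,
                             jitter = 8) {
  stopifnot(rotamers_per_type >= 1, rotamers_per_type <= 30)
  types <- unique(types[types %in% FLEXIBLE_TYPES])
  set.seed(seed)
  wells <- c(60, 180, -60)
  out <- list()
  for (rt in types) {
    k <- n_chi(rt)
    chis <- lapply(seq_len(rotamers_per_type), function(r) {
      base <- vapply(seq_len(k), function(ci)
        wells[((r - 1) + (ci - 1)) %% 3 + 1], numeric(1))
      wrap_angle(base + stats::runif(k, -jitter, jitter))
    })
    out[[rt]] <- new_rotamer_set(rt, chis,
                                 rep("library", rotamers_per_type))
  }
  structure(list(types = out,
                 provenance = sprintf("toy library (seed %d)", seed)),
            class = "rotamer_library")
}

#' Minimal element-based force-field parameters
#'
#' Lennard-Jones wells at the contact distance implied by the united-atom
#' element radii, eps = 0.1 kcal/mol everywhere, and a uniform charge
#' (default 0, making the Coulomb term vanish). Deterministic.
#'
#' @param types residue types the table must cover.
#' @param charge partial charge (e) given to every atom.
#' @param config energy-model configuration overrides.
#' @return a `forcefield`.
#' @export
make_toy_params <- function(types, charge = 0, config = list()) {
  types <- unique(c(types, "ALA", "GLY"))
  rows <- list()
  for (rt in types) {
    atoms <- c(BACKBONE_ATOMS, sidechain_atoms(rt))
    el <- atom_element(atoms)
    sigma <- 2 * VDW_RADII[el] / 2^(1 / 6)
    rows[[rt]] <- data.frame(resid = rt, elety = atoms, q = charge,
                             a = 2 * sigma^6, b = 2 * sigma^3, eps = 0.1,
                             stringsAsFactors = FALSE)
  }
  sig_o <- 2 * VDW_RADII["O"] / 2^(1 / 6)
  rows$OXT <- data.frame(resid = "*", elety = "OXT", q = charge,
                         a = 2 * sig_o^6, b = 2 * sig_o^3, eps = 0.1)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new_forcefield(tab, config)
}

#' Ideal peptide backbone
#'
#' Extended (phi, psi) = (-120, 120) by default, or helical (-57, -47);
#' trans omega throughout. Returns backbone coordinates only.
#'
#' @param n residue count.
#' @param phi,psi backbone torsions in degrees.
#' @param origin position of the first N.
#' @param direction unused reference; the strand grows along +x.
#' @return list of n 4x3 matrices (N, CA, C, O rows).
#' @export
make_toy_backbone <- function(n, phi = -120, psi = 120,
                              origin = c(0, 0, 0)) {
  N <- list()
  CA <- list()
  C <- list()
  N[[1]] <- origin
  CA[[1]] <- origin + c(1.458, 0, 0)
  C[[1]] <- place_atom(origin + c(0, 0, 1), N[[1]], CA[[1]],
                       1.525, 111.0, -120)
  for (i in seq_len(n - 1) + 1) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         1.329, 116.2, psi)
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          1.458, 121.7, 180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.0, phi)
  }
  lapply(seq_len(n), function(i) {
    o <- if (i < n) place_atom(N[[i + 1]], CA[[i]], C[[i]],
                               1.231, 120.5, 180)
         else place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 120.5, 135)
    m <- rbind(N = N[[i]], CA = CA[[i]], C = C[[i]], O = o)
    m
  })
}

# assemble a chain's atom data.frame from backbones + side-chain coords
chain_atoms <- function(bb, sidechains, types, chain, resno_start = 1L) {
  rows <- list()
  for (i in seq_along(bb)) {
    m <- rbind(bb[[i]], sidechains[[i]])
    rows[[i]] <- data.frame(chain = chain, resno = resno_start + i - 1L,
                            icode = "", resid = types[i],
                            elety = rownames(m), x = m[, 1], y = m[, 2],
                            z = m[, 3], occ = 1, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic bound/unbound case with known truth
#'
#' Chain A is an ideal strand of `types` sharing an identical backbone in
#' the bound and unbound states (zero backbone change). Bound side chains
#' sit exactly on toy-library rotamers (`bound_assignment`); unbound side
#' chains are the bound chis shifted by `unbound_perturbation` (default:
#' chi1 +120 degrees for every second flexible residue, chi2 +15 for all).
#' A poly-ALA partner strand (chain B) runs parallel 5 A away so that every
#' chain-A residue is interfacial. The bound structure holds both chains;
#' the unbound structure holds chain A alone.
#'
#' @param types residue types of chain A; the default is 8 flexible
#'   residues (small polar, branched and long side chains, including the
#'   free-slot SER/CYS path) capped by two ALA.
#' @param seed integer seed (library jitter + bound assignment draw).
#' @param rotamers_per_type toy-library size per type.
#' @param bound_assignment per-flexible-residue rotamer index (default:
#'   drawn from the seed).
#' @param unbound_perturbation list of per-flexible-residue chi shift
#'   vectors (recycled against each residue's chi count), or NULL for the
#'   default scheme.
#' @param backbone "extended" or "helical".
#' @param partner_offset perpendicular offset of the partner strand (A).
#' @return list: `bound`, `unbound` (`pdb_structure`s), `library`, `truth`
#'   (flexible residue keys, assignment indices, bound chis).
#' @export
make_toy_case <- function(types = c("ALA", "SER", "CYS", "VAL", "THR",
                                    "LEU", "ASP", "GLN", "MET", "ALA"),
                          seed = 0L, rotamers_per_type = 3L,
                          bound_assignment = NULL,
                          unbound_perturbation = NULL,
                          backbone = c("extended", "helical"),
                          partner_offset = 5) {
  backbone <- match.arg(backbone)
  lib <- make_toy_library(types, rotamers_per_type, seed)
  n <- length(types)
  ang <- if (backbone == "extended") c(-120, 120) else c(-57, -47)
  bb <- make_toy_backbone(n, ang[1], ang[2])
  flex <- which(types %in% FLEXIBLE_TYPES)
  set.seed(seed + 1L)
  if (is.null(bound_assignment))
    bound_assignment <- vapply(flex, function(i)
      sample.int(length(lib$types[[types[i]]]$chis), 1), integer(1))
  stopifnot(length(bound_assignment) == length(flex))
  if (is.null(unbound_perturbation))
    unbound_perturbation <- lapply(seq_along(flex), function(j) {
      k <- n_chi(types[flex[j]])
      shift <- numeric(k)
      if (j %% 2 == 0) shift[1] <- 120
      if (k >= 2) shift[2] <- shift[2] + 15
      shift
    })
  chis_b <- chis_u <- vector("list", n)
  sc_b <- sc_u <- vector("list", n)
  for (i in seq_len(n)) {
    rt <- types[i]
    if (!(rt %in% FLEXIBLE_TYPES)) {
      sc_b[[i]] <- sc_u[[i]] <- place_topology(bb[[i]], rt)
      next
    }
    j <- match(i, flex)
    ch <- lib$types[[rt]]$chis[[bound_assignment[j]]]
    pert <- rep_len(unbound_perturbation[[j]], length(ch))
    chis_b[[i]] <- ch
    chis_u[[i]] <- wrap_angle(ch + pert)
    sc_b[[i]] <- place_topology(bb[[i]], rt, ch)
    sc_u[[i]] <- place_topology(bb[[i]], rt, chis_u[[i]])
  }
  atoms_a_b <- chain_atoms(bb, sc_b, types, "A")
  atoms_a_u <- chain_atoms(bb, sc_u, types, "A")
  # partner: poly-ALA strand offset perpendicular to the chain direction
  bb_p <- make_toy_backbone(n, ang[1], ang[2],
                            origin = c(0, partner_offset, 0))
  sc_p <- lapply(bb_p, function(b) place_topology(b, "ALA"))
  atoms_p <- chain_atoms(bb_p, sc_p, rep("ALA", n), "B")
  bound <- structure_from_atoms(rbind(atoms_a_b, atoms_p), id = "toy_bound")
  unbound <- structure_from_atoms(atoms_a_u, id = "toy_unbound")
  truth <- list(
    flex_keys = paste("A", flex, "", sep = "."),
    types = types[flex], assignment = bound_assignment,
    chis_bound = chis_b[flex], chis_unbound = chis_u[flex])
  list(bound = bound, unbound = unbound, library = lib, truth = truth)
}
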