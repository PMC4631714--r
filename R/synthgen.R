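# Deterministic generators for synthetic charged point-cloud "molecules".
# All randomness is drawn from a locally scoped Mersenne-Twister stream
# seeded explicitly: the caller's RNG state is saved and restored, so the
# generators are pure functions of their arguments.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a synthetic charged molecule
#'
#' Builds a point-cloud molecule with prescribed geometry and per-atom
#' partial charges. Elements are set to carbon throughout — fingerprinting
#' consumes only coordinates and charges, so synthetic fixtures need no
#' chemically valid bonding. Deterministic: the same arguments always give
#' a byte-identical molecule.
#'
#' @param n_atoms number of atoms (>= 1).
#' @param geometry `"line"` (1 Angstrom spacing on x), `"ring"` (unit-area
#'   spacing on a circle of radius `n/ (2 pi)` Angstrom), `"gaussian_blob"`
#'   (isotropic Gaussian, sd `spread` Angstrom) or `"helix"` (radius 2.3 A,
#'   rise 1.5 A/turn-step).
#' @param charge_profile either a numeric vector of length `n_atoms` used
#'   verbatim, or `"tiers"` (atoms drawn uniformly from \{-0.25, 0, +0.25\}
#'   so all three default tiers are populated), or `"neutral"` (all 0).
#' @param spread geometry scale parameter (Angstrom) for `gaussian_blob`.
#' @param seed integer seed for the stochastic geometries/charges.
#' @param mol_id identifier.
#' @return a charged [molecule()].
#' @export
make_molecule <- function(n_atoms, geometry = c("line", "ring",
                                                "gaussian_blob", "helix"),
                          charge_profile = "tiers", spread = 3,
                          seed = 1L, mol_id = NULL) {
  geometry <- match.arg(geometry)
  if (n_atoms < 1) stop("make_molecule(): n_atoms must be >= 1")
  if (is.null(mol_id)) {
    mol_id <- sprintf("synth_%s_n%d_s%d", geometry, n_atoms, seed)
  }
  with_seed(seed, {
    xyz <- switch(geometry,
      line = cbind(x = (seq_len(n_atoms) - 1), y = 0, z = 0),
      ring = {
        th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
        r <- n_atoms / (2 * pi)
        cbind(x = r * cos(th), y = r * sin(th), z = 0)
      },
      gaussian_blob = matrix(stats::rnorm(3 * n_atoms, sd = spread),
                             ncol = 3, dimnames = list(NULL, c("x", "y", "z"))),
      helix = {
        t <- seq_len(n_atoms) - 1
        cbind(x = 2.3 * cos(t), y = 2.3 * sin(t), z = 1.5 * t / (2 * pi))
      })
    q <- if (is.numeric(charge_profile)) {
      if (length(charge_profile) != n_atoms) {
        stop("make_molecule(): charge_profile length must equal n_atoms")
      }
      charge_profile
    } else if (identical(charge_profile, "tiers")) {
      sample(c(-0.25, 0, 0.25), n_atoms, replace = TRUE)
    } else if (identical(charge_profile, "neutral")) {
      rep(0, n_atoms)
    } else stop("make_molecule(): unknown charge_profile")
    molecule(data.frame(element = "C", x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], charge = q,
                        stringsAsFactors = FALSE),
             mol_id = mol_id,
             source = sprintf("synthgen:%s(n=%d, seed=%d)", geometry,
                              n_atoms, seed))
  })
}

#' Perturb a molecule into a conformer at an exact RMSD
#'
#' Adds an isotropic Gaussian displacement to every atom, rescaled so that
#' the coordinate RMSD to the input equals `target_rmsd` exactly (within
#' numerical precision). Charges and all annotations are preserved.
#'
#' @param mol a [molecule()].
#' @param target_rmsd desired RMSD in Angstrom (>= 0).
#' @param seed integer seed.
#' @return the perturbed molecule (mol_id suffixed with the RMSD and seed).
#' @export
perturb_conformer <- function(mol, target_rmsd, seed = 1L) {
  if (target_rmsd < 0) stop("perturb_conformer(): target_rmsd must be >= 0")
  n <- n_atoms(mol)
  if (target_rmsd == 0 || n == 0) {
    mol$mol_id <- sprintf("%s_r%gs%d", mol$mol_id, target_rmsd, seed)
    return(mol)
  }
  with_seed(seed, {
    disp <- matrix(stats::rnorm(3 * n), ncol = 3)
    scale <- target_rmsd / sqrt(sum(disp^2) / n)
    mol <- set_coords(mol, coords(mol) + disp * scale)
    mol$mol_id <- sprintf("%s_r%gs%d", mol$mol_id, target_rmsd, seed)
    mol
  })
}

#' Apply a rigid-body transform to a molecule
#'
#' @param mol a [molecule()].
#' @param rotation 3x3 orthonormal matrix (checked to 1e-10).
#' @param translation length-3 numeric vector (Angstrom).
#' @return the transformed molecule; charges preserved.
#' @export
rigid_transform <- function(mol, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-10) {
    stop("rigid_transform(): rotation must be 3x3 orthonormal (within 1e-10)")
  }
  set_coords(mol, coords(mol) %*% t(rotation) +
               matrix(translation, n_atoms(mol), 3, byrow = TRUE))
}

# A uniformly random rotation matrix (via QR of a Gaussian matrix with
# sign-fixed diagonal), drawn from the current RNG stream.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Grouped ligand/pocket benchmark set
#'
#' Emulates a pocket-classification benchmark at desk scale: `n_groups`
#' template molecules of distinct random geometry, each expanded into
#' `per_group` small-RMSD conformers ("ligands"), and for every ligand a
#' paired synthetic "pocket" — a shell of charge-complementary points
#' placed 3--6.5 Angstrom outward from each ligand atom along the direction
#' away from the molecular centroid, mimicking a binding cleft that encodes
#' the ligand's complementary shape. Within-group conformational spread is
#' much smaller than between-group geometry differences.
#'
#' @param n_groups number of ligand groups (>= 2; default 9).
#' @param per_group members per group (>= 2; default 10).
#' @param n_atoms_range inclusive range of per-template atom counts.
#' @param conformer_rmsd within-group perturbation RMSD (Angstrom).
#' @param seed integer seed.
#' @return list with `ligands` and `pockets` (lists of [molecule()]s of
#'   equal length) and `groups` (character labels, parallel to both).
#' @export
make_grouped_benchmark <- function(n_groups = 9L, per_group = 10L,
                                   n_atoms_range = c(24L, 60L),
                                   conformer_rmsd = 0.3, seed = 1L) {
  if (n_groups < 2 || per_group < 2) {
    stop("make_grouped_benchmark(): need n_groups >= 2 and per_group >= 2")
  }
  ligands <- list(); pockets <- list(); groups <- character()
  for (g in seq_len(n_groups)) {
    g_seed <- seed * 1000L + g
    n_at <- with_seed(g_seed, {
      sample(seq(n_atoms_range[1], n_atoms_range[2]), 1)
    })
    template <- make_molecule(n_at, "gaussian_blob", charge_profile = "tiers",
                              spread = 2.5 + 0.5 * g, seed = g_seed,
                              mol_id = sprintf("g%02d_template", g))
    for (m in seq_len(per_group)) {
      lig <- perturb_conformer(template, conformer_rmsd,
                               seed = g_seed * 100L + m)
      lig$mol_id <- sprintf("g%02d_lig%02d", g, m)
      # random pose: the fingerprint must not depend on it
      lig <- with_seed(g_seed * 100L + m,
                       rigid_transform(lig, random_rotation(),
                                       stats::rnorm(3, sd = 20)))
      pk <- make_pocket_shell(lig, seed = g_seed * 100L + m)
      pk$mol_id <- sprintf("g%02d_pkt%02d", g, m)
      ligands[[length(ligands) + 1L]] <- lig
      pockets[[length(pockets) + 1L]] <- pk
      groups <- c(groups, sprintf("G%02d", g))
    }
  }
  names(ligands) <- vapply(ligands, `[[`, character(1), "mol_id")
  names(pockets) <- vapply(pockets, `[[`, character(1), "mol_id")
  list(ligands = ligands, pockets = pockets, groups = groups)
}

# Charge-complementary shell around a ligand: one point per ligand atom,
# offset radially (away from the centroid) by a distance drawn in
# [3, 6.5] Angstrom, carrying the inverted charge. Fixture semantics only.
make_pocket_shell <- function(lig, seed) {
  xyz <- coords(lig)
  ctr <- colMeans(xyz)
  dirs <- sweep(xyz, 2, ctr)
  nrm <- sqrt(rowSums(dirs^2))
  nrm[nrm < 1e-8] <- 1
  dirs <- dirs / nrm
  with_seed(seed + 7L, {
    off <- stats::runif(nrow(xyz), 3, 6.5)
    shell <- xyz + dirs * off
    molecule(data.frame(element = "C", x = shell[, 1], y = shell[, 2],
                        z = shell[, 3], charge = -charges(lig),
                        record_kind = "polymer", stringsAsFactors = FALSE),
             mol_id = paste0(lig$mol_id, "_pocket"),
             source = "synthgen:pocket_shell")
  })
}
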