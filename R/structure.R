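#' Construct a structure model
#'
#' A light container for protein coordinates: one data frame of atoms with a
#' `pos` column mapping each residue to an alignment column. The residue to
#' column map must be injective over mapped residues.
#'
#' @param atoms Data frame with columns `pos` (alignment column, integer),
#'   `res_name`, `atom` (PDB atom name, e.g. `"CA"`), `element`, `x`, `y`,
#'   `z`, `chain`.
#' @return Object of class `StructureModel`.
#' @export
structure_model <- function(atoms) {
  need <- c("pos", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms data frame must contain columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure")
  }
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$res_name)) atoms$res_name <- "ALA"
  structure(list(atoms = atoms, positions = sort(unique(atoms$pos))),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", length(x$positions), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]. Only `ATOM` records are kept;
#' for alternate locations the highest-occupancy conformer of each atom is
#' retained. Residues are mapped to alignment columns either sequentially in
#' order of appearance (default) or through an explicit TSV residue map,
#' which avoids hidden alignment heuristics.
#'
#' @param path PDB file.
#' @param resmap Optional path to a TSV with columns `resno` and `column`
#'   (and optionally `chain`): explicit residue-to-column map. Unmapped
#'   residues are dropped.
#' @param chain Optional chain identifier to restrict to.
#' @return [structure_model()].
#' @export
read_structure <- function(path, resmap = NULL, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  # highest-occupancy conformer per (chain, residue, insert, atom name);
  # original atom order is preserved
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- seq_len(nrow(at))
  pick <- ord[order(key, -occ)]
  pick <- pick[!duplicated(key[pick])]
  at <- at[sort(pick), , drop = FALSE]
  element <- at$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- substr(gsub("[0-9]", "", at$elety[blank]), 1, 1)
  reskey <- paste(at$chain, at$resno, at$insert, sep = "|")
  res_order <- unique(reskey)
  if (is.null(resmap)) {
    pos <- match(reskey, res_order)
  } else {
    map <- read.delim(resmap, stringsAsFactors = FALSE)
    if (!all(c("resno", "column") %in% names(map))) {
      stop("residue map must have columns 'resno' and 'column'")
    }
    if (anyDuplicated(map$column)) {
      stop("residue-to-column map is not injective")
    }
    if (is.null(map$chain)) {
      pos <- map$column[match(at$resno, map$resno)]
    } else {
      pos <- map$column[match(paste(at$chain, at$resno),
                              paste(map$chain, map$resno))]
    }
    keep <- !is.na(pos)
    at <- at[keep, , drop = FALSE]
    element <- element[keep]
    pos <- pos[keep]
  }
  structure_model(data.frame(
    pos = as.integer(pos), res_name = at$resid, atom = at$elety,
    element = element, x = at$x, y = at$y, z = at$z, chain = at$chain,
    stringsAsFactors = FALSE))
}

#' Write a structure model as a PDB file
#'
#' Minimal fixed-width ATOM-record writer for the package's toy structures;
#' output is readable by standard PDB parsers.
#'
#' @param model [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  at <- model$atoms
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), at$atom, at$res_name, at$chain, at$pos,
    at$x, at$y, at$z, 1.00, 0.00, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

heavy_atoms <- function(model) {
  model$atoms[!(model$atoms$element %in% c("H", "D")), , drop = FALSE]
}

coords <- function(df) {
  as.matrix(df[, c("x", "y", "z"), drop = FALSE])
}

# virtual C-beta from backbone N/CA/C ideal geometry (used for glycine and
# residues with a missing CB)
virtual_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

cb_coordinates <- function(model, cb_fallback = c("virtual", "ca")) {
  cb_fallback <- match.arg(cb_fallback)
  at <- model$atoms
  out <- matrix(NA_real_, length(model$positions), 3,
                dimnames = list(model$positions, c("x", "y", "z")))
  for (k in seq_along(model$positions)) {
    p <- model$positions[k]
    res <- at[at$pos == p, , drop = FALSE]
    cb <- res[res$atom == "CB", , drop = FALSE]
    if (nrow(cb)) {
      out[k, ] <- as.numeric(cb[1, c("x", "y", "z")])
      next
    }
    n <- res[res$atom == "N", ]
    ca <- res[res$atom == "CA", ]
    c_ <- res[res$atom == "C", ]
    if (cb_fallback == "virtual" && nrow(n) && nrow(ca) && nrow(c_)) {
      out[k, ] <- virtual_cb(as.numeric(n[1, c("x", "y", "z")]),
                             as.numeric(ca[1, c("x", "y", "z")]),
                             as.numeric(c_[1, c("x", "y", "z")]))
    } else if (nrow(ca)) {
      out[k, ] <- as.numeric(ca[1, c("x", "y", "z")])
    } else {
      warning("position ", p, " has no CB and no backbone to build one; ",
              "excluded from burial counts")
    }
  }
  out
}

#' C-beta neighbor counts per position
#'
#' Number of other residues' C-beta atoms strictly within `radius` Angstrom
#' of each position's C-beta (the residue's own C-beta is not counted).
#' Glycine, which has no C-beta, gets a virtual one built from ideal backbone
#' geometry.
#'
#' @param model [structure_model()].
#' @param radius Neighbourhood radius in Angstrom (default 8).
#' @param cb_fallback `"virtual"` (default) or `"ca"` for positions lacking a
#'   C-beta.
#' @return Named integer vector of neighbor counts, one per position.
#' @export
cb_neighbor_counts <- function(model, radius = 8, cb_fallback = "virtual") {
  cb <- cb_coordinates(model, cb_fallback)
  ok <- stats::complete.cases(cb)
  d <- as.matrix(stats::dist(cb[ok, , drop = FALSE]))
  counts <- setNames(rep(NA_integer_, nrow(cb)), rownames(cb))
  counts[ok] <- as.integer(rowSums(d < radius) - 1L)
  counts
}

#' Burial class from a C-beta neighbor count
#'
#' Bins: exposed for 0-8 neighbors, intermediate for 9-14, buried for more
#' than 14.
#'
#' @param cb_count Non-negative integer vector of neighbor counts.
#' @return Character vector: `"exposed"`, `"intermediate"` or `"buried"`.
#' @export
burial_class <- function(cb_count) {
  stopifnot(all(cb_count >= 0, na.rm = TRUE))
  out <- ifelse(cb_count <= 8, "exposed",
                ifelse(cb_count <= 14, "intermediate", "buried"))
  out[is.na(cb_count)] <- NA_character_
  out
}

#' Burial class of a position pair
#'
#' Six-way symmetric mapping: buried/buried and buried/intermediate are
#' buried pairs; exposed/buried and intermediate/intermediate are
#' intermediate pairs; exposed/intermediate and exposed/exposed are exposed
#' pairs.
#'
#' @param a,b Burial classes from [burial_class()] (vectorized).
#' @return Character vector of pair burial classes.
#' @export
pair_burial_class <- function(a, b) {
  lvl <- c(exposed = 0L, intermediate = 1L, buried = 2L)
  stopifnot(all(a %in% names(lvl) | is.na(a)), all(b %in% names(lvl) | is.na(b)))
  s <- lvl[a] + lvl[b]
  unname(c("exposed", "exposed", "intermediate", "buried", "buried")[s + 1L])
}

#' Minimum heavy-atom distance between two positions
#'
#' Minimum Euclidean distance over all pairs of non-hydrogen atoms of the two
#' residues.
#'
#' @param model [structure_model()].
#' @param i,j Alignment columns of the two residues.
#' @return Distance in Angstrom; 0 when `i == j`.
#' @export
min_heavy_atom_distance <- function(model, i, j) {
  stopifnot(inherits(model, "StructureModel"))
  if (i == j) return(0)
  at <- heavy_atoms(model)
  ai <- coords(at[at$pos == i, , drop = FALSE])
  aj <- coords(at[at$pos == j, , drop = FALSE])
  if (nrow(ai) == 0 || nrow(aj) == 0) {
    stop("missing density: no heavy atoms for position ",
         if (nrow(ai) == 0) i else j)
  }
  d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)
  sqrt(max(min(d2), 0))
}

#' Flag positions in contact with a partner atom set
#'
#' A position is flagged when any of its heavy atoms lies strictly within
#' `cutoff` Angstrom of any atom in the partner set. Used both for interface
#' positions (partner = binding-partner heavy atoms) and active-site
#' positions (partner = catalytic-residue heavy atoms).
#'
#' @param model [structure_model()].
#' @param partner_atoms Numeric matrix (n x 3) of partner heavy-atom
#'   coordinates.
#' @param cutoff Contact cutoff in Angstrom (default 6).
#' @return Named logical vector, one flag per position.
#' @export
interface_positions <- function(model, partner_atoms, cutoff = 6) {
  stopifnot(inherits(model, "StructureModel"))
  partner_atoms <- as.matrix(partner_atoms)
  if (nrow(partner_atoms) == 0) stop("empty partner atom set")
  if (ncol(partner_atoms) != 3) stop("partner_atoms must be an n x 3 matrix")
  at <- heavy_atoms(model)
  flags <- setNames(logical(length(model$positions)), model$positions)
  for (k in seq_along(model$positions)) {
    p <- model$positions[k]
    xyz <- coords(at[at$pos == p, , drop = FALSE])
    if (nrow(xyz) == 0) next
    d2 <- outer(rowSums(xyz^2), rowSums(partner_atoms^2), "+") -
      2 * xyz %*% t(partner_atoms)
    flags[k] <- min(d2) < cutoff^2
  }
  flags
}

#' Optimal-superposition RMSD between two coordinate sets
#'
#' Kabsch superposition: both point sets are centred, the optimal rotation is
#' obtained from the SVD of their covariance (with the determinant correction
#' that excludes reflections), and the RMSD of the superposed sets is
#' returned.
#'
#' @param p,q Numeric n x 3 coordinate matrices with matched rows.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(p, q) {
  p <- as.matrix(p)
  q <- as.matrix(q)
  stopifnot(ncol(p) == 3, all(dim(p) == dim(q)), nrow(p) >= 3)
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  s <- svd(crossprod(pc, qc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((pc %*% rot - qc)^2)))
}

model_ca <- function(model) {
  at <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  at <- at[order(at$pos), , drop = FALSE]
  coords(at)
}

#' Structural variation of a conformational ensemble
#'
#' Mean pairwise C-alpha RMSD (after Kabsch superposition) between `sample`
#' randomly selected members of the ensemble; with 10 or fewer members all
#' are used.
#'
#' @param ensemble List of [structure_model()] objects sharing a residue
#'   count.
#' @param sample Number of members to draw (default 10).
#' @param seed Optional seed for the member draw; the caller's RNG stream is
#'   left untouched.
#' @return Mean pairwise RMSD in Angstrom.
#' @export
structural_variation <- function(ensemble, sample = 10, seed = NULL) {
  if (length(ensemble) < 2) stop("ensemble must contain at least 2 models")
  cas <- lapply(ensemble, model_ca)
  nres <- unique(vapply(cas, nrow, integer(1)))
  if (length(nres) != 1) {
    stop("ensemble members differ in residue count: ",
         paste(nres, collapse = ", "))
  }
  idx <- with_seed(seed, {
    if (length(ensemble) > sample) {
      sort(sample.int(length(ensemble), sample))
    } else {
      seq_along(ensemble)
    }
  })
  pairs <- combn(idx, 2)
  mean(vapply(seq_len(ncol(pairs)), function(k) {
    superpose_rmsd(cas[[pairs[1, k]]], cas[[pairs[2, k]]])
  }, numeric(1)))
}
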