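#' Read an alpha-carbon backbone trace
#'
#' Extracts the CA trace of one chain from a PDB or mmCIF file (format by
#' extension), in residue order with insertion codes preserved; where
#' alternate locations exist, altloc A (or blank) is kept, one record per
#' residue.
#'
#' @param file structure file (.pdb or .cif)
#' @param chain chain identifier
#' @return a \code{backbone_trace}: list with \code{xyz} (n x 3 matrix, Å),
#'   \code{resno}, \code{ins}, \code{chain}
#' @export
read_ca_trace <- function(file, chain) {
  pdb <- if (grepl("\\.cif$", file, ignore.case = TRUE))
    bio3d::read.cif(file) else bio3d::read.pdb(file)
  atoms <- pdb$atom
  if (!chain %in% atoms$chain)
    stop("chain '", chain, "' not found; available: ",
         paste(sort(unique(atoms$chain)), collapse = ", "))
  ca <- atoms[atoms$chain == chain & atoms$elety == "CA" &
                (is.na(atoms$alt) | atoms$alt %in% c("", "A")), , drop = FALSE]
  if (nrow(ca) == 0L) stop("no alpha-carbons in chain '", chain, "'")
  ins <- ifelse(is.na(ca$insert), "", ca$insert)
  ord <- order(ca$resno, ins)
  ca <- ca[ord, , drop = FALSE]
  ins <- ins[ord]
  key <- paste(ca$resno, ins)
  keep <- !duplicated(key)
  new_backbone_trace(as.matrix(ca[keep, c("x", "y", "z")]),
                     resno = ca$resno[keep], ins = ins[keep], chain = chain)
}

#' @rdname read_ca_trace
#' @param xyz n x 3 coordinate matrix (Å)
#' @param resno residue numbers
#' @param ins insertion codes
#' @export
new_backbone_trace <- function(xyz, resno = seq_len(nrow(xyz)),
                               ins = rep("", nrow(xyz)), chain = "A") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(resno))
  structure(list(xyz = xyz, resno = resno, ins = ins, chain = chain),
            class = "backbone_trace")
}

#' @export
print.backbone_trace <- function(x, ...) {
  cat("CA trace: chain ", x$chain, ", ", nrow(x$xyz), " residues\n", sep = "")
  invisible(x)
}

#' Reflect coordinates through the yz-plane
#'
#' The geometric half of the mirror-image principle: x -> -x turns a model
#' into its enantiomer. Reflection is an isometry (all pairwise distances
#' preserved) and an involution (applying it twice restores the input
#' exactly); the signed volume of every point tetrad flips sign. Any mirror
#' plane differs from this one only by a proper rotation, so one fixed plane
#' keeps outputs reproducible. Atom names and residue identities are not
#' renamed.
#'
#' @param x an n x 3 coordinate matrix or a \code{backbone_trace}
#' @return same type as the input, reflected
#' @export
mirror_structure <- function(x) {
  if (inherits(x, "backbone_trace")) {
    x$xyz[, 1L] <- -x$xyz[, 1L]
    return(x)
  }
  x <- as.matrix(x)
  x[, 1L] <- -x[, 1L]
  x
}

#' Mirror a structure file
#'
#' Reads a PDB file, reflects all atom coordinates through the yz-plane and
#' writes the mirrored model with a header remark marking it as mirrored
#' (residue chirality labels are deliberately left unchanged).
#'
#' @param infile,outfile PDB paths
#' @export
mirror_pdb <- function(infile, outfile) {
  pdb <- bio3d::read.pdb(infile)
  xyz <- matrix(pdb$xyz, ncol = 3L, byrow = TRUE)
  xyz[, 1L] <- -xyz[, 1L]
  bio3d::write.pdb(pdb, xyz = as.vector(t(xyz)), file = outfile)
  lines <- readLines(outfile)
  writeLines(c("REMARK   6 MIRRORED MODEL: COORDINATES REFLECTED X -> -X",
               lines), outfile)
  invisible(outfile)
}

# signed dihedral (degrees) for one point quadruple, IUPAC sign convention
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m <- c(n1[2] * n2[3] - n1[3] * n2[2],
         n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
}

#' Virtual CA torsions of a backbone trace
#'
#' Dihedral angles over consecutive alpha-carbon quadruples, the classic
#' sidechain-free descriptor of backbone twist. An ideal right-handed
#' alpha-helix gives virtual torsions near +50 degrees; its mirror image
#' negates every torsion.
#'
#' @param trace a \code{backbone_trace} (or n x 3 matrix)
#' @return numeric vector of n - 3 torsions in degrees (NA where degenerate)
#' @export
virtual_torsions <- function(trace) {
  xyz <- if (inherits(trace, "backbone_trace")) trace$xyz else as.matrix(trace)
  n <- nrow(xyz)
  if (n < 4L) stop("at least 4 alpha-carbons are required for a torsion")
  vapply(seq_len(n - 3L), function(i)
    dihedral(xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ], xyz[i + 3L, ]),
    numeric(1))
}

#' Classify alpha-helix handedness from a CA trace
#'
#' Computes virtual torsions over consecutive CA quadruples and classifies
#' by their median: right-handed if it falls in [+30, +70] degrees,
#' left-handed if in [-70, -30] (windows symmetric about zero, centered on
#' the ideal alpha-helix virtual torsion of about 50 degrees), otherwise
#' \code{none}. Classification is only attempted when consecutive CA
#' spacings lie in [2.0, 4.5] Å (a broken or non-physical trace returns
#' \code{none}). L-residue alpha-helices are right-handed; the mirror-image
#' helices of D-peptides are left-handed.
#'
#' @param trace a \code{backbone_trace} or n x 3 CA coordinate matrix
#' @return list with \code{handedness} (\code{"right"}, \code{"left"} or
#'   \code{"none"}) and \code{median_torsion} in degrees
#' @export
helix_handedness <- function(trace) {
  xyz <- if (inherits(trace, "backbone_trace")) trace$xyz else as.matrix(trace)
  if (nrow(xyz) < 4L) stop("at least 4 residues are required")
  gaps <- sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                          xyz[-nrow(xyz), , drop = FALSE])^2))
  if (any(gaps < 2.0 | gaps > 4.5))
    return(list(handedness = "none", median_torsion = NA_real_))
  tor <- virtual_torsions(xyz)
  med <- median(tor, na.rm = TRUE)
  handed <- if (is.na(med)) "none"
    else if (med >= 30 && med <= 70) "right"
    else if (med >= -70 && med <= -30) "left"
    else "none"
  list(handedness = handed, median_torsion = med)
}

#' Generate an ideal alpha-helix CA trace
#'
#' Parametric helix used as a fixture: CA radius 2.3 Å, rise 1.5 Å per
#' residue, 100 degrees of twist per residue — the canonical alpha-helix
#' geometry. \code{handedness = "left"} mirrors the parametrization.
#'
#' @param n number of residues
#' @param radius,rise,twist helix parameters (Å, Å/residue, degrees/residue)
#' @param handedness \code{"right"} or \code{"left"}
#' @return a \code{backbone_trace}
#' @export
ideal_helix <- function(n = 12L, radius = 2.3, rise = 1.5, twist = 100,
                        handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  t <- (seq_len(n) - 1L) * twist * pi / 180
  xyz <- cbind(radius * cos(t), radius * sin(t), rise * (seq_len(n) - 1L))
  if (handedness == "left") xyz <- mirror_structure(xyz)
  new_backbone_trace(xyz)
}

#' Write a CA trace as a minimal PDB file
#'
#' @param trace a \code{backbone_trace}
#' @param file output path
#' @export
write_ca_pdb <- function(trace, file) {
  xyz <- trace$xyz
  bio3d::write.pdb(xyz = as.vector(t(xyz)), file = file,
                   type = rep("ATOM", nrow(xyz)),
                   resno = trace$resno, resid = rep("ALA", nrow(xyz)),
                   elety = rep("CA", nrow(xyz)),
                   chain = rep(trace$chain, nrow(xyz)))
  invisible(file)
}
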