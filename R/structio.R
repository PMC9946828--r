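#' @importFrom stats setNames
NULL

BACKBONE_ATOMS <- c("N", "CA", "C")
OPTIONAL_ATOMS <- c("O", "CB")

# Ideal virtual C-beta internal coordinates (standard ideal-geometry convention):
# CA-CB bond 1.522 A, N-CA-CB angle 110.4 deg, C-N-CA-CB dihedral -122.5 deg.
IDEAL_CB <- list(bond = 1.522, angle = 110.4, torsion = -122.5)

# Average isotopic residue (monomer) masses in Da; a free chain adds one water.
RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.01528

AA3_TO_1 <- c(
  GLY = "G", ALA = "A", SER = "S", PRO = "P", VAL = "V", THR = "T",
  CYS = "C", LEU = "L", ILE = "I", ASN = "N", ASP = "D", GLN = "Q",
  LYS = "K", GLU = "E", MET = "M", HIS = "H", PHE = "F", ARG = "R",
  TYR = "Y", TRP = "W"
)
AA1_TO_3 <- setNames(names(AA3_TO_1), unname(AA3_TO_1))

#' Construct a backbone structure object
#'
#' A `backbone` holds one protein chain as parallel vectors of residue names and
#' numbers plus per-atom coordinate matrices, and optionally hetero-group
#' (ligand) atoms. It is the common currency of the whole package: geometry
#' maps, family profiles and the fixture generator all consume and produce it.
#'
#' @param resid character vector of 3-letter residue names.
#' @param resno integer vector of residue numbers, strictly increasing.
#' @param coords named list of n x 3 coordinate matrices (Angstrom); must
#'   contain `N`, `CA`, `C`; `O` and `CB` optional (rows may be `NA` where an
#'   atom is absent).
#' @param hetero data frame of hetero atoms with columns `group`, `atom`,
#'   `x`, `y`, `z`, or `NULL`.
#' @param extra data frame of additional polymer (side-chain) atoms with
#'   columns `resno`, `atom`, `x`, `y`, `z`, or `NULL`.
#' @param chain_id single character chain identifier.
#' @return an object of class `backbone`.
#' @export
backbone <- function(resid, resno, coords, hetero = NULL, extra = NULL,
                     chain_id = "A") {
  n <- length(resid)
  stopifnot(length(resno) == n)
  if (n > 1 && any(diff(resno) <= 0)) {
    stop("residue numbers must be strictly increasing", call. = FALSE)
  }
  for (at in BACKBONE_ATOMS) {
    m <- coords[[at]]
    if (is.null(m) || nrow(m) != n || any(!is.finite(m))) {
      bad <- if (is.null(m) || nrow(m) != n) "all" else
        paste(resno[!stats::complete.cases(m)], collapse = ",")
      stop(sprintf("missing or non-finite backbone atom %s (residue %s)", at, bad),
           call. = FALSE)
    }
  }
  for (at in OPTIONAL_ATOMS) {
    if (is.null(coords[[at]])) coords[[at]] <- matrix(NA_real_, n, 3)
  }
  if (is.null(hetero)) {
    hetero <- data.frame(group = character(), atom = character(),
                         x = numeric(), y = numeric(), z = numeric())
  }
  if (is.null(extra)) {
    extra <- data.frame(resno = integer(), atom = character(),
                        x = numeric(), y = numeric(), z = numeric())
  }
  structure(list(resid = as.character(resid), resno = as.integer(resno),
                 coords = coords[c(BACKBONE_ATOMS, OPTIONAL_ATOMS)],
                 hetero = hetero, extra = extra, chain_id = chain_id),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> chain %s: %d residues, %d hetero atoms\n",
              x$chain_id, length(x$resid), nrow(x$hetero)))
  invisible(x)
}

#' @export
length.backbone <- function(x) length(x$resid)

#' Read a backbone structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations by
#' highest occupancy (ties broken alphabetically by altloc code), orders
#' residues by (number, insertion code), and returns one chain as a
#' [backbone()] object. HETATM groups (e.g. a bound ligand) are kept in
#' `$hetero`.
#'
#' @param path PDB file path.
#' @param chain chain identifier; may be omitted when the file holds a single
#'   chain.
#' @return a `backbone`.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines))) {
    stop(sprintf("no ATOM records in %s (empty or non-PDB file)", path), call. = FALSE)
  }
  # light pre-scan so malformed records are reported with their line number
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54)))))) {
      stop(sprintf("malformed PDB record at line %d of %s", i, path), call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at$chain[is.na(at$chain)] <- "A"

  prot <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(prot$chain)
  if (is.null(chain)) {
    if (length(chains) > 1) {
      stop(sprintf("file has chains %s; specify one with `chain`",
                   paste(chains, collapse = ", ")), call. = FALSE)
    }
    chain <- chains[1]
  }
  if (!chain %in% chains) {
    stop(sprintf("chain %s not present (have: %s)", chain,
                 paste(chains, collapse = ", ")), call. = FALSE)
  }
  prot <- prot[prot$chain == chain, , drop = FALSE]

  # altloc policy: keep highest occupancy, ties alphabetical
  prot$alt[is.na(prot$alt)] <- ""
  prot$insert[is.na(prot$insert)] <- ""
  key <- paste(prot$resno, prot$insert, prot$elety)
  keep <- unlist(lapply(split(seq_len(nrow(prot)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    o <- prot$o[idx]
    o[is.na(o)] <- 1
    idx <- idx[o == max(o)]
    idx[order(prot$alt[idx])][1]
  }), use.names = FALSE)
  prot <- prot[sort(keep), , drop = FALSE]

  rkey <- paste(prot$resno, prot$insert)
  ord <- order(prot$resno[!duplicated(rkey)], prot$insert[!duplicated(rkey)])
  ukeys <- rkey[!duplicated(rkey)][ord]
  n <- length(ukeys)
  resid <- character(n); resno <- integer(n)
  coords <- lapply(setNames(nm = c(BACKBONE_ATOMS, OPTIONAL_ATOMS)),
                   function(a) matrix(NA_real_, n, 3))
  extra <- list()
  for (k in seq_len(n)) {
    rows <- prot[rkey == ukeys[k], , drop = FALSE]
    resid[k] <- rows$resid[1]
    resno[k] <- rows$resno[1]
    for (a in c(BACKBONE_ATOMS, OPTIONAL_ATOMS)) {
      hit <- which(rows$elety == a)
      if (length(hit)) coords[[a]][k, ] <- as.numeric(rows[hit[1], c("x", "y", "z")])
    }
    for (a in BACKBONE_ATOMS) {
      if (anyNA(coords[[a]][k, ])) {
        stop(sprintf("residue %s %d lacks backbone atom %s", resid[k], resno[k], a),
             call. = FALSE)
      }
    }
    oth <- rows[!rows$elety %in% c(BACKBONE_ATOMS, OPTIONAL_ATOMS), , drop = FALSE]
    if (nrow(oth)) {
      extra[[length(extra) + 1L]] <- data.frame(
        resno = resno[k], atom = oth$elety, x = oth$x, y = oth$y, z = oth$z)
    }
  }
  extra <- if (length(extra)) do.call(rbind, extra) else NULL

  het <- at[at$type == "HETATM" & at$resid != "HOH", , drop = FALSE]
  hetero <- data.frame(group = het$resid, atom = het$elety,
                       x = het$x, y = het$y, z = het$z)
  backbone(resid, resno, coords, hetero = hetero, extra = extra, chain_id = chain)
}

#' Write a backbone structure to a PDB file
#'
#' Emits ATOM records for the backbone atoms (N, CA, C and, where present, O
#' and CB), HETATM records for hetero groups, and a TER record. Round-trips
#' through [read_pdb()] to PDB coordinate precision (1e-3 Angstrom).
#'
#' @param x a `backbone`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "backbone"))
  eleno <- 0L
  out <- character(0)
  fmt <- function(no, elety, resid, chain, resno, xyz, rectype = "ATOM  ") {
    elety_f <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else sprintf("%-4s", elety)
    sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            rectype, no, elety_f, resid, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0)
  }
  for (k in seq_along(x$resid)) {
    for (a in c("N", "CA", "C", "O", "CB")) {
      xyz <- x$coords[[a]][k, ]
      if (anyNA(xyz)) next
      if (a == "CB" && x$resid[k] == "GLY") next  # never deposit a glycine CB
      eleno <- eleno + 1L
      out <- c(out, fmt(eleno, a, x$resid[k], x$chain_id, x$resno[k], xyz))
    }
    ex <- x$extra[x$extra$resno == x$resno[k], , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      eleno <- eleno + 1L
      out <- c(out, fmt(eleno, ex$atom[j], x$resid[k], x$chain_id, x$resno[k],
                        as.numeric(ex[j, c("x", "y", "z")])))
    }
  }
  out <- c(out, sprintf("TER   %5d      %-3s %s%4d",
                        eleno + 1L, x$resid[length(x$resid)], x$chain_id,
                        x$resno[length(x$resno)]))
  if (nrow(x$hetero)) {
    hres <- max(x$resno) + 1L
    for (k in seq_len(nrow(x$hetero))) {
      eleno <- eleno + 1L
      out <- c(out, fmt(eleno, x$hetero$atom[k], x$hetero$group[k], x$chain_id,
                        hres, as.numeric(x$hetero[k, c("x", "y", "z")]),
                        rectype = "HETATM"))
    }
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Reconstruct C-beta positions
#'
#' Ensures every residue (including glycine) carries a C-beta coordinate, as
#' required by the C-beta-based inter-residue geometries. Observed C-beta
#' atoms of non-glycine residues are kept; missing ones (and all glycines) get
#' an ideal virtual C-beta placed from N/CA/C by fixed internal coordinates
#' (CA-CB 1.522 A, N-CA-CB 110.4 deg, C-N-CA-CB dihedral -122.5 deg).
#'
#' @param x a `backbone` whose residues all have N, CA, C.
#' @return the `backbone` with a complete CB coordinate matrix.
#' @export
reconstruct_cb <- function(x) {
  stopifnot(inherits(x, "backbone"))
  cb <- x$coords$CB
  for (k in seq_along(x$resid)) {
    if (!anyNA(cb[k, ]) && x$resid[k] != "GLY") next
    cb[k, ] <- place_atom(x$coords$C[k, ], x$coords$N[k, ], x$coords$CA[k, ],
                          IDEAL_CB$bond, IDEAL_CB$angle, IDEAL_CB$torsion)
  }
  x$coords$CB <- cb
  x
}

#' Count polymer residues
#'
#' @param x a `backbone`.
#' @return number of polymer residues (hetero groups excluded).
#' @export
residue_count <- function(x) {
  stopifnot(inherits(x, "backbone"))
  length(x$resid)
}

#' Average-isotopic mass of a protein chain
#'
#' Sum of average residue masses plus one water, in Da.
#'
#' @param sequence 1-letter amino-acid string (standard 20-letter alphabet).
#' @return mass in Da.
#' @export
chain_mass <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_MASS))
  if (length(bad)) {
    stop(sprintf("unknown amino-acid letter(s): %s", paste(unique(bad), collapse = ",")),
         call. = FALSE)
  }
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}

#' One-letter sequence of a backbone
#' @param x a `backbone`.
#' @return 1-letter amino-acid string (`X` for non-standard residues).
#' @export
backbone_sequence <- function(x) {
  stopifnot(inherits(x, "backbone"))
  l <- AA3_TO_1[x$resid]
  l[is.na(l)] <- "X"
  paste(l, collapse = "")
}

resolve_selection <- function(x, sel) {
  stopifnot(length(sel) == 2)
  atom <- as.character(sel[[2]])
  if (is.numeric(sel[[1]]) || grepl("^[0-9]+$", sel[[1]])) {
    resno <- as.integer(sel[[1]])
    k <- which(x$resno == resno)
    if (!length(k)) stop(sprintf("residue %d not found", resno), call. = FALSE)
    if (length(k) > 1) stop(sprintf("residue %d is ambiguous", resno), call. = FALSE)
    xyz <- x$coords[[atom]]
    if (!is.null(xyz) && !anyNA(xyz[k, ])) return(xyz[k, ])
    hit <- which(x$extra$resno == resno & x$extra$atom == atom)
    if (length(hit) == 1) return(as.numeric(x$extra[hit, c("x", "y", "z")]))
    if (length(hit) > 1) {
      stop(sprintf("selection %d:%s is ambiguous", resno, atom), call. = FALSE)
    }
    stop(sprintf("atom %s not found in residue %d", atom, resno), call. = FALSE)
  }
  group <- as.character(sel[[1]])
  hit <- which(x$hetero$group == group & x$hetero$atom == atom)
  if (!length(hit)) {
    stop(sprintf("hetero atom %s:%s not found", group, atom), call. = FALSE)
  }
  if (length(hit) > 1) {
    stop(sprintf("hetero selection %s:%s is ambiguous (%d atoms)", group, atom,
                 length(hit)), call. = FALSE)
  }
  as.numeric(x$hetero[hit, c("x", "y", "z")])
}

#' Distance between two selected atoms
#'
#' Selections are length-2 lists/vectors: `(residue_number, atom_name)` for
#' polymer atoms or `(group_name, atom_name)` for hetero atoms (e.g.
#' `list("DTZ", "N1")`). The "centre of the guanidinium cation" of an arginine
#' is its CZ atom, the centroid of the three guanidinium nitrogens by
#' construction.
#'
#' @param x a `backbone`.
#' @param sel_a,sel_b atom selections.
#' @return Euclidean distance in Angstrom.
#' @export
atom_distance <- function(x, sel_a, sel_b) {
  stopifnot(inherits(x, "backbone"))
  vnorm(resolve_selection(x, sel_a) - resolve_selection(x, sel_b))
}
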