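# Minimal PDB ATOM-record reader: enough of the fixed-column format to
# build a union-of-balls model with hydrophobicity classes.  No download,
# no HETATM chemistry, no symmetry.

# Bondi van der Waals radii (Angstrom) for the elements that occur in
# standard residues; unknown elements fall back to carbon.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90)

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read ATOM records from a PDB file into a ball model
#'
#' Fixed-column parsing of ATOM records only.  Element symbols come from
#' columns 77-78 when present, else from the atom name; radii from a
#' Bondi table (unknown elements get the carbon radius with a notice).
#' Atoms of fully hydrophobic residues (C, I, L, M, W, F, Y, V) get
#' hydrophobicity class 1, all others class 2.  When alternate locations
#' are present, the highest-occupancy one is kept, ties broken in favour
#' of altLoc 'A'.
#'
#' @param path PDB-format file.
#' @param chain Optional chain identifier filter.
#' @return List: \code{model} (\code{\link{ball_model}} with
#'   \code{z_protons} = 0), \code{sequence} (one-letter string over the
#'   parsed residues, 'X' for non-standard), \code{residues} (data.frame
#'   chain/resseq/resname per residue).
#' @export
read_pdb_atoms <- function(path, chain = NULL) {
  lines <- readLines(path)
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (!length(atom)) stop("no ATOM records in ", path, call. = FALSE)
  fld <- function(x, a, b) trimws(substr(x, a, b))
  df <- data.frame(
    name = fld(atom, 13, 16),
    altloc = substr(atom, 17, 17),
    resname = fld(atom, 18, 20),
    chain = substr(atom, 22, 22),
    resseq = as.integer(fld(atom, 23, 26)),
    x = as.numeric(fld(atom, 31, 38)),
    y = as.numeric(fld(atom, 39, 46)),
    z = as.numeric(fld(atom, 47, 54)),
    occ = suppressWarnings(as.numeric(fld(atom, 55, 60))),
    elem = toupper(fld(atom, 77, 78)),
    stringsAsFactors = FALSE)
  df$occ[is.na(df$occ)] <- 1
  if (!is.null(chain)) {
    df <- df[df$chain == chain, , drop = FALSE]
    if (!nrow(df)) stop("no ATOM records for chain '", chain, "'",
                        call. = FALSE)
  }
  # element fallback: first alphabetic character of the atom name
  miss <- !nzchar(df$elem)
  df$elem[miss] <- substr(gsub("[^A-Za-z].*", "", df$name[miss]), 1, 1)
  # altLoc resolution per (chain, resseq, atom name)
  if (any(df$altloc != " ")) {
    key <- paste(df$chain, df$resseq, df$name)
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
      if (length(idx) == 1L) return(idx)
      sub <- df[idx, ]
      best <- idx[sub$occ == max(sub$occ)]
      if (length(best) > 1L) {
        pref <- best[df$altloc[best] == "A"]
        if (length(pref)) best <- pref
      }
      best[1L]
    }))
    df <- df[sort(keep), , drop = FALSE]
  }
  unknown <- !df$elem %in% names(.vdw_radii)
  if (any(unknown)) {
    message("read_pdb_atoms: unknown element(s) ",
            paste(unique(df$elem[unknown]), collapse = ", "),
            "; using the carbon radius")
  }
  r <- ifelse(unknown, .vdw_radii[["C"]], .vdw_radii[df$elem])
  aa1 <- unname(.aa3to1[df$resname])
  aa1[is.na(aa1)] <- "X"
  hydrophobic <- !is.na(aa1) & aa1 %in% names(which(
    .residue_class_table == "FULL_HYDROPHOBIC"))
  m <- ball_model(df$x, df$y, df$z, r,
                  hclass = ifelse(hydrophobic, 1L, 2L), z_protons = 0,
                  class_count = 2L)
  rkey <- paste(df$chain, df$resseq)
  first <- !duplicated(rkey)
  list(model = m,
       sequence = paste(aa1[first], collapse = ""),
       residues = data.frame(chain = df$chain[first],
                             resseq = df$resseq[first],
                             resname = df$resname[first],
                             stringsAsFactors = FALSE))
}
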