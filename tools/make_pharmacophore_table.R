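# Generates inst/extdata/pharmacophores.tsv: the eight-class pharmacophore
# assignment for every heavy atom of the 20 standard residues (plus OXT).
source("R/geometry.R"); source("R/templates.R")
suppressMessages(library(tibble))

AROMATIC <- list(
  PHE = c("CG","CD1","CD2","CE1","CE2","CZ"),
  TYR = c("CG","CD1","CD2","CE1","CE2","CZ"),
  TRP = c("CG","CD1","NE1","CE2","CD2","CE3","CZ2","CZ3","CH2"),
  HIS = c("CG","ND1","CD2","CE1","NE2")
)
POSITIVE <- list(LYS = "NZ", ARG = c("NE","NH1","NH2"), HIS = c("ND1","NE2"))
NEGATIVE <- list(ASP = c("OD1","OD2"), GLU = c("OE1","OE2"))
DONOR <- list(LYS = "NZ", ARG = c("NE","NH1","NH2"), HIS = c("ND1","NE2"),
              TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
              TYR = "OH", CYS = "SG")
ACCEPTOR <- list(ASP = c("OD1","OD2"), GLU = c("OE1","OE2"), ASN = "OD1",
                 GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
                 HIS = c("ND1","NE2"), MET = "SD")
SULFUR <- list(CYS = "SG", MET = "SD")
# amide/carboxyl/guanidinium carbons: sp2 carbons bonded only to heteroatom groups
NEUTRAL_C <- list(ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD", ARG = "CZ")

rows <- list()
for (res in names(SIDECHAIN_Z)) {
  atoms <- c(residue_template(res)$atom, "OXT")
  for (at in atoms) {
    el <- atom_element(at)
    cls <- character()
    in_set <- function(tab) res %in% names(tab) && at %in% tab[[res]]
    if (in_set(AROMATIC)) cls <- c(cls, "aromatic")
    if (in_set(POSITIVE)) cls <- c(cls, "positive")
    if (at == "OXT") cls <- c(cls, "negative") else if (in_set(NEGATIVE)) cls <- c(cls, "negative")
    if (at == "N" && res != "PRO") cls <- c(cls, "donor") else if (in_set(DONOR)) cls <- c(cls, "donor")
    if (at %in% c("O", "OXT")) cls <- c(cls, "acceptor") else if (in_set(ACCEPTOR)) cls <- c(cls, "acceptor")
    if (in_set(SULFUR)) cls <- c(cls, "sulfur")
    if (el == "C" && !("aromatic" %in% cls)) {
      if (at == "C" || in_set(NEUTRAL_C)) cls <- c(cls, "neutral") else cls <- c(cls, "hydrophobic")
    }
    if (length(cls) == 0) cls <- "neutral"  # e.g. PRO N
    rows[[length(rows) + 1]] <- tibble(resname = res, atom = at,
                                       class = paste(sort(unique(cls)), collapse = ","))
  }
}
tab <- do.call(rbind, rows)
tab <- tab[order(tab$resname, tab$atom), ]
header <- c("# Pharmacophore atom classes, version 1",
            "# resname\tatom\tclass (comma-separated subset of: hydrophobic,positive,negative,acceptor,donor,aromatic,sulfur,neutral)")
writeLines(c(header, paste(tab$resname, tab$atom, tab$class, sep = "\t")),
           "inst/extdata/pharmacophores.tsv")
cat("wrote", nrow(tab), "rows\n")
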