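# Standard (nuclear) genetic code and memoised Nei-Gojobori codon tables.
# The code table is fixed: the pipeline analyses nuclear transcripts only.

.BASES <- c("A", "C", "G", "T")

.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]

translate_codon <- function(codon) {
  aa <- .GENETIC_CODE[codon]
  if (any(is.na(aa))) stop("not a valid codon: ",
                           paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

is_stop_codon <- function(codon) codon %in% .STOP_CODONS

# all 64 codons in a fixed order; index arithmetic used by the memo tables
.ALL_CODONS <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
.ALL_CODONS <- sort(.ALL_CODONS)

codon_index <- function(codon) match(codon, .ALL_CODONS)

# Memoised per-codon synonymous site counts and per-pair difference counts.
# Built once per session; 64 codons / 64x64 pairs, so the cost is trivial.
ng_tables <- function() {
  if (!is.null(.spinsex_cache$ng)) return(.spinsex_cache$ng)
  s_sites <- rep(NA_real_, 64L)
  names(s_sites) <- .ALL_CODONS
  for (cd in .ALL_CODONS) {
    if (is_stop_codon(cd)) next
    s_sites[cd] <- ng_sites(cd)[["s"]]
  }
  sd <- matrix(NA_real_, 64L, 64L, dimnames = list(.ALL_CODONS, .ALL_CODONS))
  nd <- sd
  for (a in .ALL_CODONS) {
    if (is_stop_codon(a)) next
    for (b in .ALL_CODONS) {
      if (is_stop_codon(b)) next
      d <- ng_differences(a, b)
      sd[a, b] <- d[["sd"]]
      nd[a, b] <- d[["nd"]]
    }
  }
  .spinsex_cache$ng <- list(s_sites = s_sites, sd = sd, nd = nd)
  .spinsex_cache$ng
}
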