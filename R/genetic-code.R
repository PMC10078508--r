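# Genetic-code helpers built on the NCBI translation tables shipped with
# Biostrings. The invertebrate mitochondrial code (table 5: ATA=Met,
# TGA=Trp, AGA/AGG=Ser, stops TAA/TAG) is the package default.

# cache per code id: list(code = named chr[64], stops, families, ng_sites)
.code_cache <- new.env(parent = emptyenv())

#' Fetch an NCBI genetic code as a codon -> amino-acid map
#'
#' @param code_id NCBI translation table id (integer or string). Default 5,
#'   the invertebrate mitochondrial code.
#' @return named character vector of length 64; names are DNA codons, values
#'   one-letter amino acids with `"*"` for stop.
#' @examples
#' genetic_code(5)[c("ATA", "TGA", "AGA")] # M, W, S under the mito code
#' @export
genetic_code <- function(code_id = 5) {
  Biostrings::getGeneticCode(as.character(code_id))
}

code_info <- function(code_id = 5) {
  key <- as.character(code_id)
  if (!is.null(.code_cache[[key]])) {
    return(.code_cache[[key]])
  }
  code <- genetic_code(key)
  stops <- names(code)[code == "*"]
  aas <- setdiff(unique(code), "*")
  families <- lapply(setNames(aas, aas), function(a) names(code)[code == a])
  info <- list(
    code = code, stops = stops, families = families,
    degeneracy = vapply(families, length, integer(1)),
    ng_sites = ng_site_table(code)
  )
  .code_cache[[key]] <- info
  info
}

is_stop_codon <- function(codon, code) unname(code[codon] == "*")

# Nei-Gojobori per-codon synonymous site counts: at each codon position the
# three alternative bases are classified synonymous/nonsynonymous; changes
# creating stop codons are dropped from the denominator so every position
# still contributes exactly one site (keeps N + S = 3 x codons).
ng_site_table <- function(code) {
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (code[[cd]] == "*") {
      syn[[cd]] <- NA_real_
      next
    }
    s <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(bases, substr(cd, pos, pos)), function(b) {
        alt <- cd
        substr(alt, pos, pos) <- b
        alt
      }, character(1))
      keep <- alts[code[alts] != "*"]
      if (length(keep) > 0L) {
        s <- s + sum(code[keep] == code[[cd]]) / length(keep)
      }
    }
    syn[[cd]] <- s
  }
  syn
}
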