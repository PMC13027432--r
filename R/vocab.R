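#' Canonical PTM type vocabulary and synonym normalization
#'
#' PTM annotation databases spell modification types inconsistently
#' ("Phosphorylation", "phospho", "O-GlcNAc", ...). All functions in this
#' package key sites by a canonical lower-case, underscore-separated type
#' string. `ptm_vocabulary()` returns the shipped table of canonical types
#' with their synonyms; `normalize_ptm_type()` maps arbitrary spellings onto
#' it. Types that do not resolve to a canonical entry are passed through in
#' normalized spelling and flagged `nonstandard` rather than dropped, so an
#' extended catalog never silently misclassifies.
#'
#' @return `ptm_vocabulary()`: a tibble with columns `ptm_type` (canonical),
#'   `synonyms` (semicolon-joined alternate spellings).
#' @export
#' @examples
#' normalize_ptm_type(c("Phosphorylation", "phospho", "O-GlcNAcylation"))
ptm_vocabulary <- function() {
  tibble::tribble(
    ~ptm_type, ~synonyms,
    "phosphorylation",        "phospho;phosphorylated;p",
    "acetylation",            "acetyl;ac;n6_acetyllysine",
    "ubiquitination",         "ubiquitylation;ubiquitin;ub;ubi",
    "methylation",            "methyl;me;mono_methylation",
    "sumoylation",            "sumo;sumoylated",
    "succinylation",          "succinyl",
    "malonylation",           "malonyl",
    "glutarylation",          "glutaryl",
    "glutathionylation",      "s_glutathionylation;glutathione",
    "s_nitrosylation",        "nitrosylation;sno",
    "s_palmitoylation",       "palmitoylation;palmitoyl",
    "sulfoxidation",          "methionine_sulfoxidation;met_oxidation",
    "n_linked_glycosylation", "n_glycosylation;nglyco;n_glyco",
    "o_linked_glycosylation", "o_glycosylation;o_glcnacylation;o_glcnac;oglyco",
    "neddylation",            "nedd8",
    "hydroxylation",          "hydroxy",
    "adp_ribosylation",       "adp_ribose;parylation",
    "carbamidation",          "carbamylation",
    "deamidation",            "deamidated",
    "farnesylation",          "farnesyl",
    "geranylgeranylation",    "geranylgeranyl",
    "gpi_anchor",             "gpi_anchor_addition;gpi",
    "lipoylation",            "lipoyl",
    "pyruvation",             "pyruvate_addition",
    "oxidation",              "oxidized",
    "biotinylation",          "biotinyl",
    "dephosphorylation",      "dephospho",
    "crotonylation",          "crotonyl",
    "citrullination",         "deimination"
  )
}

#' @rdname ptm_vocabulary
#' @param x character vector of PTM type spellings as found in source tables.
#' @return `normalize_ptm_type()`: a character vector of canonical type
#'   strings, with attribute `nonstandard` listing input spellings that did
#'   not resolve to the shipped vocabulary.
#' @export
normalize_ptm_type <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  norm <- gsub("^_+|_+$", "", gsub("_+", "_", gsub("[^a-z0-9]+", "_", raw)))
  vocab <- ptm_vocabulary()
  syn_map <- stats::setNames(
    rep(vocab$ptm_type, lengths(strsplit(vocab$synonyms, ";", fixed = TRUE))),
    unlist(strsplit(vocab$synonyms, ";", fixed = TRUE))
  )
  out <- ifelse(norm %in% vocab$ptm_type, norm,
                ifelse(norm %in% names(syn_map), unname(syn_map[norm]), norm))
  nonstandard <- sort(unique(norm[!(out %in% vocab$ptm_type)]))
  attr(out, "nonstandard") <- nonstandard
  out
}

#' Default residue eligibility map for PTM types
#'
#' The PTM potentiality rate normalizes observed site counts to the number of
#' residues chemically able to carry the modification (e.g. lysine for
#' acetylation; serine, threonine and tyrosine for phosphorylation). This
#' returns the default eligibility alphabet per canonical type, following
#' standard residue chemistry. Types not listed here fall back, inside
#' [ptm_potentiality()], to the residues actually observed for that type in
#' the catalog at hand.
#'
#' @return named list mapping canonical `ptm_type` to a character vector of
#'   one-letter residue codes.
#' @export
#' @examples
#' default_eligibility()[["phosphorylation"]]
default_eligibility <- function() {
  list(
    phosphorylation        = c("S", "T", "Y"),
    acetylation            = "K",
    ubiquitination         = "K",
    sumoylation            = "K",
    methylation            = c("K", "R"),
    succinylation          = "K",
    malonylation           = "K",
    glutarylation          = "K",
    s_nitrosylation        = "C",
    glutathionylation      = "C",
    s_palmitoylation       = "C",
    sulfoxidation          = "M",
    n_linked_glycosylation = "N",
    o_linked_glycosylation = c("S", "T"),
    neddylation            = "K",
    hydroxylation          = c("P", "K"),
    crotonylation          = "K",
    citrullination         = "R"
  )
}

# Canonical amino-acid alphabet (20 one-letter codes).
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
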