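#' Mitonuclear genotype labels
#'
#' A mitonuclear genotype is written as a two-character label, the nuclear
#' background first and the mitochondrial background second ("ND" carries
#' the N nucleus and the D mitochondrion). Background identifiers are single
#' characters drawn from a configured set (default N, D, Y).
#'
#' @param nuclear,mitochondrial single-character background identifiers.
#' @param backgrounds character vector of allowed background identifiers.
#' @return `mitonuclear_genotype()` returns the two-character label.
#' @examples
#' mitonuclear_genotype("N", "D")
#' genotype_nuclear("ND")
#' @export
mitonuclear_genotype <- function(nuclear, mitochondrial,
                                 backgrounds = c("N", "D", "Y")) {
  stopifnot(nchar(nuclear) == 1L, nchar(mitochondrial) == 1L)
  if (!all(c(nuclear, mitochondrial) %in% backgrounds))
    stop("background identifiers must come from the configured set: ",
         paste(backgrounds, collapse = ", "))
  paste0(nuclear, mitochondrial)
}

#' @rdname mitonuclear_genotype
#' @param label two-character genotype label.
#' @export
genotype_nuclear <- function(label) substr(label, 1L, 1L)

#' @rdname mitonuclear_genotype
#' @export
genotype_mito <- function(label) substr(label, 2L, 2L)

#' The seven mitonuclear backgrounds of the default design
#' @export
default_genotypes <- function() c("NN", "ND", "DN", "DD", "DY", "YD", "YY")

#' Evolutionary circumstances
#'
#' One circumstance is the combination of a mitonuclear genotype and an
#' evolution medium (FF fermentable, NF nonfermentable). Seven genotypes
#' crossed with two media give the 14 circumstances of the default design.
#'
#' @param genotypes character vector of genotype labels.
#' @param media character vector of medium codes.
#' @return data.frame with columns circumstance, genotype, nuclear, mito,
#'   medium; one row per genotype x medium combination.
#' @examples
#' nrow(circumstance_table())  # 14
#' @export
circumstance_table <- function(genotypes = default_genotypes(),
                               media = c("FF", "NF")) {
  grid <- expand.grid(genotype = genotypes, medium = media,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    circumstance = paste(grid$genotype, grid$medium, sep = "."),
    genotype = grid$genotype,
    nuclear = genotype_nuclear(grid$genotype),
    mito = genotype_mito(grid$genotype),
    medium = grid$medium,
    stringsAsFactors = FALSE
  )
}
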