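#' Genotype algebra for the three enzyme-production loci
#'
#' A genotype carries three binary loci, one per nutrient (C, N, P), each
#' either a producer allele (capital letter) or a non-producer allele
#' (lowercase). The genotype \code{"CNp"} produces C- and N-enzymes but not
#' P-enzymes; \code{"cnp"} is the pure cheater. Locus order in names is
#' always C, N, P.
#'
#' Internally a genotype is an integer vector of three 0/1 flags with class
#' \code{"enz_genotype"}; the integer code used in rasters is
#' \code{produces_C*4 + produces_N*2 + produces_P + 1} (so \code{cnp} = 1,
#' \code{CNP} = 8, and 0 denotes an empty box).
#'
#' @param name A 3-character string over \code{{C,c}{N,n}{P,p}} in that
#'   locus order, e.g. \code{"CnP"}.
#' @return `parse_genotype()` returns an `enz_genotype` object.
#' @examples
#' g <- parse_genotype("CNp")
#' format(g)
#' complementation_score(parse_genotype("CNp"), parse_genotype("Cnp"))
#' @export
parse_genotype <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      nchar(name) != 3L) {
    stop("genotype name must be a single 3-character string, got ",
         deparse(name), call. = FALSE)
  }
  chars <- strsplit(name, "")[[1]]
  expect <- c("C", "N", "P")
  flags <- integer(3)
  for (i in 1:3) {
    if (chars[i] == expect[i]) {
      flags[i] <- 1L
    } else if (chars[i] == tolower(expect[i])) {
      flags[i] <- 0L
    } else {
      stop("invalid character '", chars[i], "' at locus ", expect[i],
           " in genotype name '", name, "' (expected '", expect[i],
           "' or '", tolower(expect[i]), "')", call. = FALSE)
    }
  }
  new_genotype(flags)
}

new_genotype <- function(flags) {
  structure(as.integer(flags), names = c("C", "N", "P"),
            class = "enz_genotype")
}

#' @param x,g An `enz_genotype` object.
#' @param ... Unused.
#' @rdname parse_genotype
#' @export
format.enz_genotype <- function(x, ...) {
  up <- c("C", "N", "P")
  flags <- unclass(x)
  paste0(ifelse(flags == 1L, up, tolower(up)), collapse = "")
}

#' @export
print.enz_genotype <- function(x, ...) {
  cat("<genotype ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @export
`==.enz_genotype` <- function(e1, e2) {
  all(unclass(e1) == unclass(e2))
}

#' Integer raster code of a genotype
#'
#' @rdname parse_genotype
#' @export
genotype_code <- function(g) {
  stopifnot(inherits(g, "enz_genotype"))
  g[[1]] * 4L + g[[2]] * 2L + g[[3]] + 1L
}

#' All eight genotype names
#'
#' Names are ordered by raster code: \code{cnp} (code 1) through \code{CNP}
#' (code 8).
#'
#' @return Character vector of length 8.
#' @export
genotype_names <- function() {
  vapply(1:8, function(code) {
    bits <- c(code - 1L) %/% c(4L, 2L, 1L) %% 2L
    format(new_genotype(bits))
  }, character(1))
}

genotype_from_code <- function(code) {
  stopifnot(code >= 1L, code <= 8L)
  new_genotype((code - 1L) %/% c(4L, 2L, 1L) %% 2L)
}

#' Complementation score between two genotypes
#'
#' The number of enzyme loci (0--3) at which two genotypes carry different
#' alleles: the Hamming distance between their producer-flag vectors. Pairs
#' with high complementation produce disjoint enzyme sets and are candidate
#' coalition partners.
#'
#' @param a,b `enz_genotype` objects or genotype name strings.
#' @return Integer in 0..3; symmetric in its arguments.
#' @examples
#' complementation_score("CNp", "Cnp") # 1
#' complementation_score("cnP", "CNp") # 3
#' @export
complementation_score <- function(a, b) {
  if (is.character(a)) a <- parse_genotype(a)
  if (is.character(b)) b <- parse_genotype(b)
  sum(unclass(a) != unclass(b))
}

#' Mutate a genotype
#'
#' Each locus flips independently to its complementary allele with
#' probability `rate`. Draws come from R's global RNG stream.
#'
#' @param g An `enz_genotype` or genotype name.
#' @param rate Per-locus flip probability in \[0, 1\].
#' @return A (possibly unchanged) `enz_genotype`.
#' @export
mutate_genotype <- function(g, rate) {
  if (is.character(g)) g <- parse_genotype(g)
  stopifnot(rate >= 0, rate <= 1)
  flips <- stats::runif(3) < rate
  new_genotype(ifelse(flips, 1L - unclass(g), unclass(g)))
}
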