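#' Packaged example data files
#'
#' Plain-text data shipped with the package:
#' \describe{
#'   \item{`landcover_areas.csv`}{Published class-area table (ha) for the
#'     study territory in 1958 (CNR-TCI soil-use map, re-coded to CLC) and
#'     1990/2000/2006/2012/2018 (CORINE Land Cover level III); "NA" marks
#'     classes not recorded by the source map of that year.}
#'   \item{`esa_shares_synthetic.csv`}{Synthetic stand-in for the MEDALUS
#'     ESA class-share survey of 1960/2000/2020: the published headline
#'     values (not-affected 14.3/70/35%, critical 3 falling from 25% to 0%)
#'     are honoured and the remaining classes are filled so each year sums
#'     to 100%.}
#'   \item{`germination_reference_summary.csv`}{Published treatment-level
#'     germination statistics (mean and sd over four replicate dishes) for
#'     the four dormancy-breaking treatments, used as a reference for
#'     internal-consistency checks and simulator calibration.}
#' }
#'
#' @param file file name within the package's `extdata`; with no argument,
#'   lists the available files.
#' @return full path to the file (or a vector of file names).
#' @examples
#' read_landcover(seedtrends_example("landcover_areas.csv"))[1:3, ]
#' @export
seedtrends_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "seedtrends")))
  }
  path <- system.file("extdata", file, package = "seedtrends")
  if (path == "") stop("no packaged file called ", file, call. = FALSE)
  path
}
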