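#' Write / read a spectra set as CSV
#'
#' Wide dialect (written): first column `wavenumber_cm-1`, one column per
#' observation. The long dialect (`wavenumber_cm-1`, `obs_id`, `absorbance`)
#' is also accepted on read.
#'
#' @param spectra observations x wavenumbers matrix (rownames = obs ids).
#' @param wavenumber grid matching the columns.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(spectra, wavenumber, path) {
  stopifnot(ncol(spectra) == length(wavenumber))
  out <- data.frame(wavenumber, t(spectra), check.names = FALSE)
  names(out)[1] <- "wavenumber_cm-1"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @return `read_spectra_csv`: list with `spectra` (obs x wavenumber matrix)
#'   and `wavenumber`.
#' @export
read_spectra_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (all(c("obs_id", "absorbance") %in% names(d))) { # long dialect
    wn <- sort(unique(d[["wavenumber_cm-1"]]))
    ids <- unique(d$obs_id)
    m <- matrix(NA_real_, length(ids), length(wn),
                dimnames = list(ids, wn))
    m[cbind(match(d$obs_id, ids), match(d[["wavenumber_cm-1"]], wn))] <-
      d$absorbance
    return(list(spectra = m, wavenumber = wn))
  }
  wn <- d[[1]]
  m <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(m) <- wn
  list(spectra = m, wavenumber = wn)
}

#' Write an RGB image array (0-255) as PNG
#' @param img height x width x 3 array, 0-255.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a PNG image into the package's 0-255 array convention
#' @param path PNG path.
#' @return height x width x 3 array, 0-255.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}
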