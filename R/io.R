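#' Plain-text persistence of voxel images
#'
#' Volumes are written as a JSON header (dimensions, spacing, origin, role)
#' next to a flat whitespace-separated value file in column-major order.
#' A deliberately simple, dependency-free interchange format.
#'
#' @param img a \code{voxel_image}.
#' @param path base path; \code{path.json} and \code{path.txt.gz} are
#'   written.
#' @return invisibly, the two paths.
#' @export
write_voxel_image <- function(img, path) {
  stopifnot(inherits(img, "voxel_image"))
  jpath <- paste0(path, ".json")
  vpath <- paste0(path, ".txt.gz")
  jsonlite::write_json(list(dim = dim(img$values), spacing = img$spacing,
                            origin = img$origin, role = img$role),
                       jpath, auto_unbox = FALSE, digits = NA)
  con <- gzfile(vpath, "w")
  writeLines(format(as.vector(img$values), trim = TRUE, digits = 10), con)
  close(con)
  invisible(c(jpath, vpath))
}

#' @rdname write_voxel_image
#' @export
read_voxel_image <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.numeric(readLines(gzfile(paste0(path, ".txt.gz"))))
  voxel_image(array(vals, dim = hdr$dim), hdr$spacing, hdr$origin, hdr$role)
}
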