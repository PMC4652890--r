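# Surface textures: random checkerboards, 1/f noise fields and user images.
# A texture is a grid of brightness values in [0, 1] with a physical texel
# size; generation is a pure function of (kind, parameters, seed).

new_texture <- function(grid, texel_size_mm, kind, seed = NA_integer_,
                        levels = NULL) {
  stopifnot(is.matrix(grid), all(grid >= 0), all(grid <= 1),
            texel_size_mm > 0)
  structure(list(grid = grid, texel_size_mm = texel_size_mm, kind = kind,
                 seed = seed, levels = levels), class = "ca_texture")
}

# run code under a temporary RNG state so texture generation neither disturbs
# nor depends on the caller's RNG
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random black-and-white checkerboard texture
#'
#' Each texel is independently black or white with probability 1/2, the
#' pattern used on the arena walls (1, 4, 8 or 35 mm texels in the reference
#' experiments).
#'
#' @param texel_size_mm edge length of one texel (mm).
#' @param extent_mm numeric 2-vector, c(width, height) of the surface (mm);
#'   the grid has \code{ceiling(extent / texel)} texels per side.
#' @param seed integer RNG seed; the same (size, extent, seed) reproduces the
#'   identical grid.
#' @param levels brightness of the two texel classes (default black 0 and
#'   white 1); greyish variants are used on floors and ceilings.
#' @return A \code{ca_texture}.
#' @export
texture_checkerboard <- function(texel_size_mm, extent_mm, seed,
                                 levels = c(0, 1)) {
  stopifnot(texel_size_mm > 0, all(extent_mm > 0), length(extent_mm) == 2,
            length(levels) == 2)
  nc <- ceiling(extent_mm[1] / texel_size_mm)
  nr <- ceiling(extent_mm[2] / texel_size_mm)
  stopifnot(nr >= 1, nc >= 1)
  g <- with_seed(seed,
    matrix(sample(levels, nr * nc, replace = TRUE), nr, nc))
  new_texture(g, texel_size_mm, "checkerboard", seed, levels)
}

#' Random texture with 1/f amplitude statistics
#'
#' Grayscale noise whose radially averaged amplitude spectrum falls off
#' approximately as 1/f, mimicking the second-order statistics of natural
#' scenes; rescaled to [0, 1].
#'
#' @param extent_mm numeric 2-vector c(width, height) in mm.
#' @param seed integer RNG seed.
#' @param texel_size_mm sampling resolution of the field (mm).
#' @return A \code{ca_texture}.
#' @export
texture_one_over_f <- function(extent_mm, seed, texel_size_mm = 1) {
  stopifnot(all(extent_mm > 0), texel_size_mm > 0)
  nc <- ceiling(extent_mm[1] / texel_size_mm)
  nr <- ceiling(extent_mm[2] / texel_size_mm)
  g <- with_seed(seed, {
    ph <- matrix(stats::runif(nr * nc, 0, 2 * pi), nr, nc)
    fx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
    fy <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
    f <- sqrt(outer(fy^2, fx^2, `+`))
    amp <- 1 / pmax(f, 1e-12)
    amp[1, 1] <- 0
    fld <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE))
    (fld - min(fld)) / (max(fld) - min(fld))
  })
  new_texture(g, texel_size_mm, "one_over_f", seed)
}

#' Texture from a grayscale image matrix or PNG file
#'
#' Stands in for natural textures (e.g. grass): any grayscale image can be
#' used on arena surfaces.
#'
#' @param x numeric matrix in [0, 1] or path to a PNG file.
#' @param texel_size_mm physical edge of one pixel (mm).
#' @return A \code{ca_texture}.
#' @export
texture_from_image <- function(x, texel_size_mm = 1) {
  if (is.character(x)) {
    img <- png::readPNG(x)
    if (length(dim(img)) == 3) img <- img[, , 1]
    x <- img
  }
  new_texture(x, texel_size_mm, "image")
}

#' @export
print.ca_texture <- function(x, ...) {
  cat(sprintf("<ca_texture %s: %d x %d texels of %g mm, seed %s>\n",
              x$kind, nrow(x$grid), ncol(x$grid), x$texel_size_mm,
              if (is.na(x$seed %||% NA)) "-" else x$seed))
  invisible(x)
}

#' Write / read a texture as an 8-bit grayscale PNG with a sidecar record
#'
#' The sidecar (same path with extension \code{.meta.yml}) records the texel
#' size, kind and seed so that a texture round-trips.
#'
#' @param texture a \code{ca_texture}.
#' @param path PNG file path.
#' @return \code{write_texture} returns \code{path} invisibly;
#'   \code{read_texture} returns a \code{ca_texture}.
#' @export
write_texture <- function(texture, path) {
  png::writePNG(texture$grid, path)
  meta <- list(texel_size_mm = texture$texel_size_mm, kind = texture$kind,
               seed = if (is.na(texture$seed %||% NA)) NULL else texture$seed)
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_texture
#' @export
read_texture <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3) g <- g[, , 1]
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  new_texture(g, meta$texel_size_mm, meta$kind %||% "image",
              meta$seed %||% NA_integer_)
}
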