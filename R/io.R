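#' Read a PGM image (plain P2 or binary P5)
#'
#' Minimal netpbm grayscale reader; no pre-installed package handles PGM, and
#' plain P2 is the text fixture format used throughout the test-suite.
#'
#' @param path File path.
#' @return Integer matrix \[height, width\] of gray levels (0..maxval).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # token reader skipping whitespace and '#' comments
  next_token <- function() {
    tok <- character(0)
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1))
      if (!length(ch) || ch == "") stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1))
          if (ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  n <- w * h
  if (magic == "P5") {
    vals <- if (maxval < 256) as.integer(readBin(con, "raw", n))
            else readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a PGM image
#'
#' @param img Numeric/integer matrix \[height, width\].
#' @param path File path.
#' @param maxval Maximum gray value (default 255).
#' @param ascii Write plain-text P2 (default) rather than binary P5.
#' @export
write_pgm <- function(img, path, maxval = 255L, ascii = TRUE) {
  img <- round_half_up(pmin(pmax(img, 0), maxval))
  h <- nrow(img); w <- ncol(img)
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), as.character(maxval)), con)
    writeLines(apply(img, 1, function(r) paste(as.integer(r), collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(w, h), as.character(maxval)), con)
    writeBin(as.raw(as.integer(t(img))), con)
  }
  invisible(path)
}

#' Read an edge or intensity image (PNG or PGM)
#'
#' PNG via the `png` package (first channel, rescaled to 0..255), PGM via
#' [read_pgm()]. For edge maps any nonzero pixel counts as an edge.
#'
#' @param path File path ending in .png or .pgm.
#' @param binarize Return a 0/1 integer edge map?
#' @return Matrix \[height, width\].
#' @export
read_image <- function(path, binarize = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a * 255
    },
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext)
  )
  if (binarize) matrix(as.integer(img != 0), nrow(img), ncol(img)) else img
}

#' Write an image (PNG or PGM by extension)
#' @param img Matrix \[height, width\], gray levels 0..255.
#' @param path Output path (.png or .pgm).
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(pmin(pmax(img / 255, 0), 1), path),
    pgm = write_pgm(img, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Write detections to CSV
#'
#' Schema: `x,y,kind,flipped,theta_idx,d_idx,row_idx,score`.
#' @param detections Data.frame of detections.
#' @param path Output path.
#' @export
write_detections <- function(detections, path) {
  cols <- c("x", "y", "kind", "flipped", "theta_idx", "d_idx", "row_idx", "score")
  for (cl in setdiff(cols, names(detections))) detections[[cl]] <- NA
  utils::write.csv(detections[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detections (or ground truth) from CSV
#'
#' Any CSV with at least `x` and `y` columns is accepted, so user-supplied
#' ground-truth lists work unchanged.
#' @param path CSV path.
#' @return Data.frame.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) stop("CSV needs x and y columns: ", path)
  df
}

#' Write scene ground truth to CSV (`x,y,kind,angle`)
#' @param scene An `ht3d_scene`.
#' @param path Output path.
#' @export
write_ground_truth <- function(scene, path) {
  utils::write.csv(scene_ground_truth(scene), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' One section per module: `hough` (arguments of [hough_spec()] except the
#' image size), `patterns` (arguments of [pattern_params()]) and `snn`
#' (arguments of [snn_params()]). Missing sections or keys fall back to the
#' package defaults, which are the reference parameter set.
#'
#' @param path YAML file path (or NULL for all defaults).
#' @return A list with elements `hough`, `patterns`, `snn` (argument lists).
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- list(
    hough = c("delta_d", "delta_p", "delta_theta", "eta"),
    patterns = c("tau_F", "tau_E", "lateral_cells", "phi_min", "phi_max"),
    snn = c("w_cE", "rho_p1", "rho_p2", "theta_p1", "theta_p2", "lambda",
            "corner_angle_min", "corner_angle_max", "inhibition_window",
            "edge_gating", "endpoint_threshold")
  )
  out <- list()
  for (sec in names(known)) {
    got <- cfg[[sec]]
    if (is.null(got)) got <- list()
    bad <- setdiff(names(got), known[[sec]])
    if (length(bad)) stop("unknown config keys in [", sec, "]: ", paste(bad, collapse = ", "))
    out[[sec]] <- got
  }
  out
}
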