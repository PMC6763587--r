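#' Electrode montage
#'
#' A montage holds the electrode labels of a cap together with idealized
#' unit-sphere 3D positions (head modelled as a unit sphere, vertex at
#' `(0, 0, 1)`, `+y` anterior, `+x` left). Positions are normalized to unit
#' Euclidean norm on construction; spherical-spline interpolation and the
#' synthetic generator's posterior alpha weighting both consume these
#' positions.
#'
#' @param labels character vector of unique electrode labels.
#' @param positions numeric matrix (`length(labels)` x 3) of positions; each
#'   row is normalized to unit norm (rows with norm 0 are an error).
#' @param layout_kind `"equidistant64"` (dry cap) or `"tentwenty64"`
#'   (extended 10-20 gel cap) or `"custom"`.
#' @return An object of class `"montage"`: list with `labels`, `positions`
#'   (rownames = labels) and `layout_kind`.
#' @export
montage <- function(labels, positions, layout_kind = "custom") {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("montage labels must be unique", call. = FALSE)
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels) || ncol(positions) != 3) {
    stop("positions must be a length(labels) x 3 matrix", call. = FALSE)
  }
  if (any(!is.finite(positions))) {
    stop("montage positions must be finite", call. = FALSE)
  }
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm < 1e-12)) {
    stop("montage positions must be nonzero (cannot normalize)", call. = FALSE)
  }
  positions <- positions / nrm
  rownames(positions) <- labels
  colnames(positions) <- c("x", "y", "z")
  structure(
    list(labels = labels, positions = positions, layout_kind = layout_kind),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes, layout '%s'\n",
              length(x$labels), x$layout_kind))
  invisible(x)
}

#' Read a montage from delimited text
#'
#' Expects a whitespace- or comma-delimited text file with four columns:
#' label, x, y, z (no header, or a header line starting with `#`). Positions
#' are normalized to the unit sphere on load.
#'
#' @param path file path.
#' @param layout_kind layout tag stored on the montage.
#' @return A [montage()].
#' @export
read_montage <- function(path, layout_kind = "custom") {
  if (!file.exists(path)) stop("montage file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) {
    stop("montage file must have 4 columns (label x y z); offending line: ",
         lines[which(bad)[1]], call. = FALSE)
  }
  labels <- vapply(parts, `[[`, "", 1L)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(pos))) stop("non-numeric montage coordinates", call. = FALSE)
  montage(labels, pos, layout_kind)
}

#' Write a montage as delimited text
#'
#' @param m a [montage()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  lines <- sprintf("%s %.*f %.*f %.*f", m$labels,
                   17, m$positions[, 1], 17, m$positions[, 2], 17, m$positions[, 3])
  writeLines(lines, path)
  invisible(path)
}

# spherical linear interpolation between unit vectors
slerp <- function(a, b, t) {
  dotab <- max(-1, min(1, sum(a * b)))
  ang <- acos(dotab)
  if (ang < 1e-12) return(a)
  (sin((1 - t) * ang) * a + sin(t * ang) * b) / sin(ang)
}

# unit vector at polar angle phi from the vertex, in the direction psi
# measured from anterior (+y) toward the left (+x); mirror=-1 for right side
cap_dir <- function(phi_deg, psi_deg, mirror = 1) {
  phi <- phi_deg * pi / 180
  psi <- psi_deg * pi / 180
  c(mirror * sin(phi) * sin(psi), sin(phi) * cos(psi), cos(phi))
}

#' Idealized extended 10-20 montage with 64 electrodes
#'
#' Constructs the conventional gel-cap layout (extended international 10-20
#' nomenclature, 62 scalp electrodes plus the two mastoids) on an idealized
#' spherical head: midline electrodes at 18 degree steps of polar angle,
#' the outer 10% ring at 72 degrees, intermediate electrodes by great-circle
#' interpolation between the midline and the ring, mastoids below the
#' equator. Geometry is an idealization for interpolation and simulation,
#' not a digitized cap.
#'
#' @return A [montage()] with `layout_kind = "tentwenty64"`.
#' @export
montage_tentwenty64 <- function() {
  lab <- character(0); pos <- NULL
  add <- function(l, v) {
    lab <<- c(lab, l); pos <<- rbind(pos, v)
  }
  ring <- function(off) 72 # outer ring polar angle
  # midline: polar angles anterior (psi=0) / posterior (psi=180)
  add("Fpz", cap_dir(72, 0)); add("Fz", cap_dir(36, 0)); add("FCz", cap_dir(18, 0))
  add("Cz", c(0, 0, 1))
  add("CPz", cap_dir(18, 180)); add("Pz", cap_dir(36, 180))
  add("POz", cap_dir(54, 180)); add("Oz", cap_dir(72, 180))
  # outer ring psi offsets (degrees from anterior midline), left side
  ring_psi <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
                TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  for (side in c(1, -1)) {
    nm <- names(ring_psi)
    if (side == -1) {
      nm <- sub("7", "8", nm); nm <- sub("1$", "2", nm)
    }
    for (i in seq_along(ring_psi)) add(nm[i], cap_dir(72, ring_psi[i], side))
  }
  # interior rows: slerp between the midline electrode and the ring electrode
  row_spec <- list(
    list(mid = cap_dir(54, 0),   ringpsi = 36,  labs = c("AF3"),             fr = c(1 / 2)),
    list(mid = cap_dir(36, 0),   ringpsi = 54,  labs = c("F1", "F3", "F5"),  fr = c(1, 2, 3) / 4),
    list(mid = cap_dir(18, 0),   ringpsi = 72,  labs = c("FC1", "FC3", "FC5"), fr = c(1, 2, 3) / 4),
    list(mid = c(0, 0, 1),       ringpsi = 90,  labs = c("C1", "C3", "C5"),  fr = c(1, 2, 3) / 4),
    list(mid = cap_dir(18, 180), ringpsi = 108, labs = c("CP1", "CP3", "CP5"), fr = c(1, 2, 3) / 4),
    list(mid = cap_dir(36, 180), ringpsi = 126, labs = c("P1", "P3", "P5"),  fr = c(1, 2, 3) / 4),
    list(mid = cap_dir(54, 180), ringpsi = 144, labs = c("PO3", "PO5"),      fr = c(1, 2) / 3)
  )
  for (rw in row_spec) {
    for (side in c(1, -1)) {
      ringv <- cap_dir(72, rw$ringpsi, side)
      labs <- rw$labs
      if (side == -1) {
        labs <- vapply(labs, function(l) {
          n <- as.integer(sub("^[A-Za-z]+", "", l))
          sub("[0-9]+$", as.character(n + 1L), l)
        }, "")
      }
      for (i in seq_along(labs)) add(labs[i], slerp(rw$mid, ringv, rw$fr[i]))
    }
  }
  add("M1", cap_dir(108, 100, 1)); add("M2", cap_dir(108, 100, -1))
  montage(lab, pos, "tentwenty64")
}

#' Idealized equidistant 64-electrode dry-cap montage
#'
#' Places 64 electrodes quasi-uniformly (Fibonacci lattice) over a spherical
#' cap extending 110 degrees of polar angle from the vertex, emulating the
#' equidistant layout of a 64-channel dry multipin cap. Labels are
#' `D01`..`D64`, ordered from vertex to rim.
#'
#' @return A [montage()] with `layout_kind = "equidistant64"`.
#' @export
montage_equidistant64 <- function() {
  n <- 64
  # Fibonacci lattice on the cap z in [cos(110 deg), 1]
  zmin <- cos(110 * pi / 180)
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - zmin) * i / n
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * sin(th), y = r * cos(th), z = z)
  montage(sprintf("D%02d", seq_len(n)), pos, "equidistant64")
}

#' Check that a montage covers a set of channel labels
#' @param m a [montage()].
#' @param labels channel labels that must all be present in the montage.
#' @return `TRUE` invisibly; error if any label is missing.
#' @export
montage_covers <- function(m, labels) {
  miss <- setdiff(labels, m$labels)
  if (length(miss)) {
    stop("montage is missing positions for channels: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
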