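#' Fragment configuration library for trimer replacement moves
#'
#' A fragment configuration is the 6 backbone dihedrals (phi, psi) of 3
#' consecutive residues excised from a known structure.  The library maps
#' each window start index i in 1..(n-2) (1-based; window covers residues
#' i..i+2) to a non-empty list of configurations.  Two construction modes
#' are supported:
#' \describe{
#'   \item{position-independent (default)}{every trimer excised from every
#'     source structure is available at every window;}
#'   \item{position-specific}{the trimer at source position i is assigned to
#'     window i only (requires sources of the same length as the chain).}
#' }
#'
#' @name fragment_library
NULL

new_fragment_library <- function(n, windows, mode) {
  if (n < 3) stop("chain length must be >= 3")
  if (length(windows) != n - 2) stop("window count must equal n - 2")
  if (any(vapply(windows, length, integer(1)) == 0))
    stop("window ", which(vapply(windows, length, integer(1)) == 0)[1],
         " has zero fragment configurations")
  structure(list(n = as.integer(n), windows = windows, mode = mode),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("fragment_library: n =", x$n, ", mode =", x$mode, ",",
      length(x$windows), "windows,",
      sum(vapply(x$windows, length, integer(1))), "entries\n")
  invisible(x)
}

# a single entry: numeric length-6 (phi1 psi1 phi2 psi2 phi3 psi3) + source id
fragment_config <- function(angles, source = "unknown") {
  if (length(angles) != 6) stop("a fragment configuration has 6 angles")
  ok <- angles == ANGLE_UNDEF | (is.finite(angles) & angles >= -180 & angles < 180)
  if (!all(ok)) stop("fragment angles must lie in [-180, 180) or be the sentinel")
  list(angles = as.numeric(angles), source = as.character(source))
}

# all trimer (phi,psi) windows measurable from one structure's coordinates
excise_trimers <- function(xyz, source = "struct") {
  ang <- measure_dihedrals(xyz)
  n <- length(ang$phi)
  if (n < 3) return(list())
  out <- vector("list", n - 2)
  for (i in seq_len(n - 2)) {
    a <- c(ang$phi[i], ang$psi[i], ang$phi[i + 1], ang$psi[i + 1],
           ang$phi[i + 2], ang$psi[i + 2])
    out[[i]] <- fragment_config(a, sprintf("%s:%d", source, i))
  }
  out
}

#' Build a fragment library from source structures
#'
#' Trimer (phi, psi) configurations are excised from each source structure's
#' backbone coordinates.  Terminal trimers naturally carry the undefined-
#' angle sentinel in their first phi / last psi slot; sentinel slots are
#' skipped when a configuration is applied (\code{\link{apply_move}}).
#'
#' @param structures List of 4m x 3 backbone coordinate matrices (or
#'   \code{conformation} objects, converted via forward kinematics).
#' @param n Target chain length (number of residues) the library serves.
#' @param mode \code{"position-independent"} (default) or
#'   \code{"position-specific"}.
#' @param sources Optional character vector of source identifiers.
#' @return A \code{fragment_library}.
#' @export
build_library <- function(structures, n,
                          mode = c("position-independent", "position-specific"),
                          sources = NULL) {
  mode <- match.arg(mode)
  if (length(structures) == 0) stop("empty structure set")
  if (n < 3) stop("target chain length must be >= 3")
  if (is.null(sources)) sources <- paste0("struct", seq_along(structures))
  tri <- vector("list", length(structures))
  for (s in seq_along(structures)) {
    x <- structures[[s]]
    if (inherits(x, "conformation")) x <- forward_kinematics(x)
    tri[[s]] <- excise_trimers(x, sources[s])
  }
  windows <- vector("list", n - 2)
  if (mode == "position-independent") {
    all_tri <- do.call(c, tri)
    if (length(all_tri) == 0) stop("no trimer extractable from any source")
    for (i in seq_len(n - 2)) windows[[i]] <- all_tri
  } else {
    for (i in seq_len(n - 2)) {
      ent <- list()
      for (s in seq_along(tri))
        if (length(tri[[s]]) >= i) ent <- c(ent, list(tri[[s]][[i]]))
      if (length(ent) == 0)
        stop("window ", i, " has zero extractable fragment configurations")
      windows[[i]] <- ent
    }
  }
  new_fragment_library(n, windows, mode)
}

#' Sample a fragment-replacement move
#'
#' The window start index is sampled uniformly over 1..(n-2), then a
#' configuration is sampled uniformly over the entries available at that
#' window.  Uses the current R RNG stream.
#'
#' @param lib A \code{fragment_library}.
#' @return List with \code{window} (1-based start index) and \code{config}.
#' @export
sample_move <- function(lib) {
  stopifnot(inherits(lib, "fragment_library"))
  nw <- length(lib$windows)
  i <- if (nw == 1) 1L else sample.int(nw, 1)
  ent <- lib$windows[[i]]
  j <- if (length(ent) == 1) 1L else sample.int(length(ent), 1)
  list(window = i, config = ent[[j]])
}

#' Apply a fragment-replacement move to a conformation
#'
#' Copies the configuration's 6 dihedrals over residues i..i+2.  Slots
#' carrying the undefined-angle sentinel — either in the configuration or at
#' the chain termini (phi of residue 1, psi of residue n) — are left
#' untouched, so only defined angles are overwritten.
#'
#' @param conf A \code{conformation}.
#' @param i Window start index, 1-based, 1 <= i <= n-2.
#' @param config A fragment configuration (from \code{\link{sample_move}} or
#'   \code{fragment_config}).
#' @return A new \code{conformation}; at most 6 angle slots differ.
#' @export
apply_move <- function(conf, i, config) {
  stopifnot(inherits(conf, "conformation"))
  n <- n_residues(conf)
  if (i < 1 || i > n - 2) stop("window index out of range")
  a <- config$angles
  phi <- conf$phi; psi <- conf$psi
  for (k in 0:2) {
    r <- i + k
    pv <- a[2 * k + 1]; sv <- a[2 * k + 2]
    if (pv != ANGLE_UNDEF && r != 1) phi[r] <- pv
    if (sv != ANGLE_UNDEF && r != n) psi[r] <- sv
  }
  # conf and config are already validated, so rebuild without re-validating
  structure(list(sequence = conf$sequence, phi = phi, psi = psi),
            class = "conformation")
}

#' Write a fragment library to its plain-text format
#'
#' Header lines \code{#mode} and \code{#n}, then one line per entry:
#' window index, the 6 angles, and the source id, whitespace-separated.
#'
#' @param lib A \code{fragment_library}.
#' @param file Path to write.
#' @export
write_fragment_library <- function(lib, file) {
  stopifnot(inherits(lib, "fragment_library"))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(paste("#mode", lib$mode), paste("#n", lib$n)), con)
  for (i in seq_along(lib$windows))
    for (e in lib$windows[[i]])
      writeLines(paste(i, paste(sprintf("%.17g", e$angles), collapse = " "),
                       e$source), con)
  invisible(NULL)
}

#' Read a fragment library from its plain-text format
#'
#' Strict inverse of \code{\link{write_fragment_library}}: malformed headers,
#' out-of-range windows, or empty windows are errors.
#'
#' @param file Path to a library file.
#' @return A \code{fragment_library}.
#' @export
read_fragment_library <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 3 || !startsWith(lines[1], "#mode ") ||
      !startsWith(lines[2], "#n "))
    stop("malformed fragment library file: missing #mode / #n header")
  mode <- sub("^#mode ", "", lines[1])
  if (!mode %in% c("position-independent", "position-specific"))
    stop("unknown library mode: ", mode)
  n <- as.integer(sub("^#n ", "", lines[2]))
  if (is.na(n) || n < 3) stop("invalid chain length in library header")
  windows <- replicate(n - 2, list(), simplify = FALSE)
  for (ln in lines[-(1:2)]) {
    if (!nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) < 8) stop("malformed library entry: ", ln)
    i <- as.integer(tok[1])
    if (is.na(i) || i < 1 || i > n - 2)
      stop("library entry window index out of range: ", ln)
    ang <- as.numeric(tok[2:7])
    if (any(is.na(ang))) stop("malformed angles in library entry: ", ln)
    src <- paste(tok[-(1:7)], collapse = " ")
    windows[[i]] <- c(windows[[i]], list(fragment_config(ang, src)))
  }
  new_fragment_library(n, windows, mode)
}
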