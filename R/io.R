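#' Read the backbone of one chain from a PDB file
#'
#' Parses the file with \pkg{bio3d}, restricts to the requested chain and
#' model, keeps the first altloc of each atom, and retains only residues
#' carrying all four modeled backbone heavy atoms (N, CA, C, O); residues
#' missing any of them are dropped with a warning.
#'
#' @param file Path to a PDB file.
#' @param chain Chain identifier; NULL takes the first chain present.
#' @param model Model number for multi-model (e.g. NMR) entries
#'   (default 1).
#' @return Object of class \code{structure_record}: \code{source},
#'   \code{chain}, \code{model}, \code{xyz} (4m x 3, rows N/CA/C/O per
#'   residue), \code{sequence} (one-letter), \code{resno} (original PDB
#'   residue numbers).
#' @export
read_pdb_backbone <- function(file, chain = NULL, model = 1) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at_rows <- which(at$chain == chain & at$elety %in% c("N", "CA", "C", "O") &
                     at$type %in% c("ATOM"))
  if (length(at_rows) == 0) stop("chain ", chain, " not found in ", file)
  at <- at[at_rows, , drop = FALSE]
  # first altloc per (residue, atom name)
  keep <- !duplicated(paste(at$resno, at$insert, at$elety))
  at <- at[keep, , drop = FALSE]
  xyz_rows <- at_rows[keep]
  nmod <- nrow(pdb$xyz)
  if (model < 1 || model > nmod) stop("model ", model, " not present")
  xyz_all <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)

  resnos <- unique(at$resno)
  ok_res <- vapply(resnos, function(r) {
    all(c("N", "CA", "C", "O") %in% at$elety[at$resno == r])
  }, logical(1))
  if (any(!ok_res))
    warning("dropping ", sum(!ok_res),
            " residue(s) missing backbone atoms: ",
            paste(resnos[!ok_res], collapse = ", "))
  resnos <- resnos[ok_res]
  if (length(resnos) == 0) stop("no residue with a complete backbone in ", file)

  m <- length(resnos)
  xyz <- matrix(NA_real_, 4 * m, 3)
  seq1 <- character(m)
  for (i in seq_len(m)) {
    rows <- which(at$resno == resnos[i])
    ord <- rows[match(c("N", "CA", "C", "O"), at$elety[rows])]
    xyz[(i - 1) * 4 + 1:4, ] <- xyz_all[xyz_rows[ord], , drop = FALSE]
    seq1[i] <- bio3d::aa321(at$resid[rows[1]])
  }
  rownames(xyz) <- paste(rep(c("N", "CA", "C", "O"), m),
                         rep(seq_len(m), each = 4), sep = "_")
  structure(list(source = file, chain = chain, model = model, xyz = xyz,
                 sequence = seq1, resno = resnos),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat("structure_record:", length(x$sequence), "residues, chain", x$chain,
      "from", x$source, "\n")
  invisible(x)
}

#' Convert a structure record to a conformation
#'
#' Measures phi/psi from the record's coordinates.  Note that rebuilding
#' coordinates from the resulting conformation imposes idealized geometry,
#' so absolute coordinates change slightly while dihedrals are preserved.
#'
#' @param record A \code{structure_record}.
#' @return A \code{conformation}.
#' @export
as_conformation <- function(record) {
  ang <- measure_dihedrals(record$xyz)
  n <- length(ang$phi)
  phi <- ang$phi; psi <- ang$psi
  phi[1] <- ANGLE_UNDEF; psi[n] <- ANGLE_UNDEF
  if (any(phi[-1] == ANGLE_UNDEF) || any(psi[-n] == ANGLE_UNDEF))
    stop("undefined interior dihedral; chain may have breaks")
  conformation(record$sequence, phi, psi)
}

#' Restrict two structure records to their shared residue numbers
#'
#' Start/goal correspondence is positional over the intersection of ordered
#' residue numbers; a report of dropped residues is attached.
#'
#' @param a,b \code{structure_record}s.
#' @return List with restricted records \code{a} and \code{b}.
#' @export
align_records <- function(a, b) {
  shared <- intersect(a$resno, b$resno)
  if (length(shared) < 3)
    stop("fewer than 3 shared residue numbers between ", a$source, " and ",
         b$source, "; offending residues: ",
         paste(union(setdiff(a$resno, b$resno), setdiff(b$resno, a$resno)),
               collapse = ", "))
  restrict <- function(r) {
    keep <- match(shared, r$resno)
    rows <- as.vector(t(outer(keep - 1, 1:4, function(i, j) i * 4 + j)))
    r$xyz <- r$xyz[rows, , drop = FALSE]
    r$sequence <- r$sequence[keep]
    r$resno <- r$resno[keep]
    r
  }
  list(a = restrict(a), b = restrict(b))
}

#' Write a path as a multi-model PDB
#'
#' Model k holds the backbone of the k-th conformation from root to goal.
#'
#' @param result A \code{planner_result}.
#' @param path One element of \code{\link{extract_paths}} output.
#' @param file Output path.
#' @param geo Geometry parameters.
#' @export
write_path_pdb <- function(result, path, file, geo = geometry_params()) {
  tr <- result$tree
  confs <- lapply(path$nodes, function(k) tr$conf[[k]])
  n <- n_residues(confs[[1]])
  xyz <- t(vapply(confs, function(cf)
    as.vector(t(forward_kinematics(cf, geo))), numeric(12 * n)))
  if (length(confs) == 1) xyz <- matrix(xyz, nrow = 1)
  aa3 <- vapply(confs[[1]]$sequence, bio3d::aa123, character(1))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = rep(seq_len(n), each = 4),
                   resid = rep(aa3, each = 4),
                   eleno = seq_len(4 * n),
                   elety = rep(c("N", "CA", "C", "O"), n),
                   chain = rep("A", 4 * n))
  invisible(NULL)
}

# ---- run configuration files ----------------------------------------------

config_keys <- c("tol", "max_nodes", "m", "l", "scheme", "epsilon",
                 "combine_p", "local_bias", "step_control", "use_shape_grid",
                 "shape_cell_size", "reactive", "w", "d1", "d2",
                 "start_index", "temp_index", "seed", "max_iter_factor",
                 "stop_on_goal", "energy", "funnel_scale", "barrier_height",
                 "barrier_width")

#' Read a flat key-value run configuration file
#'
#' One \code{key value} (or \code{key = value}) pair per line; \code{#}
#' starts a comment.  Unknown keys are errors.
#'
#' @param file Path.
#' @return Named list of raw string values.
#' @export
read_run_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    tok <- strsplit(sub("=", " ", ln, fixed = TRUE), "[[:space:]]+")[[1]]
    if (length(tok) != 2) stop("malformed config line: ", ln)
    if (!tok[1] %in% config_keys) stop("unknown config key: ", tok[1])
    out[[tok[1]]] <- tok[2]
  }
  out
}

#' Write a run configuration file
#' @param cfg Named list (string-coercible values).
#' @param file Path.
#' @export
write_run_config <- function(cfg, file) {
  bad <- setdiff(names(cfg), config_keys)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  writeLines(paste(names(cfg), vapply(cfg, as.character, character(1))), file)
  invisible(NULL)
}

# build planner_config + energy model from raw config strings
config_from_strings <- function(raw, start, goal, seed_override = NULL) {
  num <- function(k, d) if (is.null(raw[[k]])) d else as.numeric(raw[[k]])
  int <- function(k, d) if (is.null(raw[[k]])) d else as.integer(raw[[k]])
  lgl <- function(k, d) if (is.null(raw[[k]])) d else
    as.logical(toupper(raw[[k]]))
  chr <- function(k, d) if (is.null(raw[[k]])) d else raw[[k]]
  seed <- if (!is.null(seed_override)) as.integer(seed_override)
          else int("seed", NULL)
  cfg <- planner_config(
    tol = num("tol", 1), max_nodes = int("max_nodes", 1000),
    m = int("m", 10), l = int("l", 100),
    scheme = chr("scheme", "QUAD"), epsilon = num("epsilon", 1e-6),
    combine_p = num("combine_p", 0.9),
    local_bias = lgl("local_bias", FALSE),
    step_control = lgl("step_control", FALSE),
    use_shape_grid = lgl("use_shape_grid", FALSE),
    shape_cell_size = num("shape_cell_size", 0.25),
    reactive = lgl("reactive", FALSE),
    reactive_cfg = reactive_config(w = int("w", 100), d1 = num("d1", 0.25),
                                   d2 = num("d2", 1.5),
                                   start_index = int("start_index", 9)),
    temp_index = int("temp_index", 9), seed = seed,
    max_iter_factor = num("max_iter_factor", 50),
    stop_on_goal = lgl("stop_on_goal", FALSE))
  model <- switch(chr("energy", "amw"),
                  zero = energy_zero(),
                  funnel = energy_goal_funnel(goal,
                                              scale = num("funnel_scale", 1)),
                  barrier = energy_barrier(start, goal,
                                           height = num("barrier_height", 10),
                                           width = num("barrier_width", 1.5),
                                           scale = num("funnel_scale", 1)),
                  amw = energy_amw(),
                  stop("unknown energy model: ", chr("energy", "amw")))
  list(config = cfg, model = model)
}

# ---- command-line entry point ----------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("missing value for --", key)
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

cli_usage <- function() {
  paste("usage: pathtree-cli --start start.pdb --goal goal.pdb",
        "[--chain A] [--goal-chain A] [--library frags.txt | --sources a.pdb,b.pdb]",
        "--config run.cfg --out outdir [--seed 1] [--repeats 1]")
}

#' Command-line entry point
#'
#' Thin driver over the package functions: reads start/goal PDBs,
#' establishes residue correspondence, loads or builds the fragment
#' library, runs the planner \code{repeats} times with seeds
#' \code{seed .. seed+repeats-1}, and writes the tree log, best-path PDB,
#' depth/breadth/proximity tables, temperature trace, and a summary with
#' mean and standard deviation of depth across repeats.
#'
#' @param args Character vector of command-line arguments (flag/value
#'   pairs; see the usage string printed on error).
#' @return Integer exit status: 0 on success, 1 on error (with a
#'   diagnostic on stderr).
#' @export
cli_run <- function(args) {
  status <- tryCatch({
    opt <- parse_cli_args(args)
    req <- c("start", "goal", "config", "out")
    miss <- setdiff(req, names(opt))
    if (length(miss))
      stop("missing required flag(s): ", paste0("--", miss, collapse = ", "),
           "\n", cli_usage())
    seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
    repeats <- if (is.null(opt$repeats)) 1L else as.integer(opt$repeats)

    rec_s <- read_pdb_backbone(opt$start, chain = opt$chain)
    rec_g <- read_pdb_backbone(opt$goal,
                               chain = if (is.null(opt[["goal-chain"]]))
                                 opt$chain else opt[["goal-chain"]])
    al <- align_records(rec_s, rec_g)
    start <- as_conformation(al$a); goal <- as_conformation(al$b)
    n <- n_residues(start)

    if (!is.null(opt$library)) {
      lib <- read_fragment_library(opt$library)
      if (lib$n != n) stop("library chain length ", lib$n,
                           " does not match structures (", n, ")")
    } else if (!is.null(opt$sources)) {
      srcs <- strsplit(opt$sources, ",")[[1]]
      lib <- build_library(lapply(srcs, function(f)
        read_pdb_backbone(f)$xyz), n, sources = basename(srcs))
    } else {
      # default: library excised from the two endpoint structures
      lib <- build_library(list(al$a$xyz, al$b$xyz), n,
                           sources = c("start", "goal"))
    }

    raw <- read_run_config(opt$config)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

    depths <- numeric(repeats)
    for (r in seq_len(repeats)) {
      cm <- config_from_strings(raw, start, goal,
                                seed_override = seed + r - 1L)
      res <- run_planner(start, goal, lib, cm$model, cm$config)
      depths[r] <- tree_depth(res)
      tag <- sprintf("run%d", r)
      utils::write.table(res$log,
                         file.path(opt$out, paste0(tag, "_tree_log.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(
        data.frame(window = seq_along(res$window_best),
                   best_lrmsd = res$window_best,
                   temp_index = res$temp_trace[-1][seq_along(res$window_best)]),
        file.path(opt$out, paste0(tag, "_temperature_trace.tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- extract_paths(res)
      summ <- data.frame(metric = c("depth", "n_paths", "breadth"),
                         value = c(depths[r], length(paths),
                                   if (length(paths))
                                     path_breadth(res, paths)$b else NA))
      utils::write.table(summ,
                         file.path(opt$out, paste0(tag, "_analysis.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (length(paths))
        write_path_pdb(res, paths[[1]],
                       file.path(opt$out, paste0(tag, "_best_path.pdb")))
    }
    utils::write.table(
      data.frame(run = c(seq_len(repeats), "mean", "sd"),
                 depth = c(sprintf("%.6f", depths),
                           sprintf("%.6f", mean(depths)),
                           sprintf("%.6f", stats::sd(depths)))),
      file.path(opt$out, "depth_summary.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    0L
  }, error = function(e) {
    message("pathtree-cli error: ", conditionMessage(e))
    1L
  })
  status
}
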