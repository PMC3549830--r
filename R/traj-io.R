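# Trajectory containers and multi-frame XYZ / multi-model PDB I/O.

#' Create a single molecular configuration
#'
#' A configuration holds one frame of a solvated system: the solute point set
#' `X` (one row per solute atom) and the solvent point set `Y` (one row per
#' solvent molecule -- for water, the oxygen position). All solvent-based
#' operations in this package are invariant under permutation of the rows of
#' `Y`; the solvent molecules are indistinguishable.
#'
#' @param solute numeric matrix `m x 3` of solute atom coordinates (length
#'   units of the source file, conventionally Angstrom).
#' @param solvent numeric matrix `n x 3` of solvent positions; may have zero
#'   rows.
#' @param frame_index positive integer frame number (1-based).
#' @return An object of class `configuration`.
#' @examples
#' conf <- configuration(matrix(rnorm(9), 3, 3), matrix(rnorm(15), 5, 3))
#' conf
#' @export
configuration <- function(solute, solvent, frame_index = 1L) {
  solute <- as_coord_matrix(solute, "solute")
  solvent <- as_coord_matrix(solvent, "solvent", allow_empty = TRUE)
  if (nrow(solute) < 1L) {
    stop("configuration requires at least one solute atom", call. = FALSE)
  }
  if (!all(is.finite(solute)) || !all(is.finite(solvent))) {
    stop("configuration coordinates must all be finite", call. = FALSE)
  }
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 1L) {
    stop("frame_index must be a positive integer", call. = FALSE)
  }
  structure(
    list(solute = solute, solvent = solvent, frame_index = frame_index),
    class = "configuration"
  )
}

as_coord_matrix <- function(x, what, allow_empty = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) {
    if (!allow_empty) stop(what, " coordinates must be non-empty", call. = FALSE)
    return(matrix(numeric(0), 0L, 3L))
  }
  if (ncol(x) != 3L) {
    stop(what, " coordinates must be an n x 3 matrix", call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf(
    "<configuration> frame %d: %d solute atoms, %d solvent molecules\n",
    x$frame_index, nrow(x$solute), nrow(x$solvent)
  ))
  invisible(x)
}

#' Create a trajectory
#'
#' An ordered sequence of [configuration()] frames sampled at a fixed time
#' interval (the lag time `tau` of the elementary MSM step). All frames must
#' share the same solute atom count `m` and solvent count `n`.
#'
#' @param frames list of `configuration` objects in temporal order.
#' @param lag_time positive frame interval in time units (metadata only;
#'   transition counting works in integer frame lags).
#' @param trajectory_id character label.
#' @param box optional numeric length-3 orthorhombic box edges; when present,
#'   solvent-signature distances use the minimum-image convention.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(frames, lag_time = 1, trajectory_id = "traj", box = NULL) {
  if (length(frames) < 1L) stop("trajectory must contain at least one frame", call. = FALSE)
  ok <- vapply(frames, inherits, logical(1), what = "configuration")
  if (!all(ok)) stop("all frames must be configuration objects", call. = FALSE)
  m <- vapply(frames, function(f) nrow(f$solute), integer(1))
  n <- vapply(frames, function(f) nrow(f$solvent), integer(1))
  if (length(unique(m)) != 1L || length(unique(n)) != 1L) {
    stop("all frames must share the same solute and solvent atom counts", call. = FALSE)
  }
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (any(diff(idx) <= 0L)) {
    # renumber sequentially rather than fail: generators build frames 1..N
    for (i in seq_along(frames)) frames[[i]]$frame_index <- i
  }
  if (!is.numeric(lag_time) || length(lag_time) != 1L || lag_time <= 0) {
    stop("lag_time must be a positive scalar", call. = FALSE)
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive edge lengths", call. = FALSE)
    }
  }
  structure(
    list(frames = frames, lag_time = lag_time,
         trajectory_id = as.character(trajectory_id), box = box),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf(
    "<trajectory '%s'> %d frames (m = %d solute, n = %d solvent), lag time %g%s\n",
    x$trajectory_id, length(x$frames), nrow(f1$solute), nrow(f1$solvent),
    x$lag_time, if (is.null(x$box)) "" else ", periodic box"
  ))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Number of frames across one or more trajectories
#' @param trajs a `trajectory` or list of trajectories.
#' @return integer frame count.
#' @export
n_frames <- function(trajs) {
  sum(vapply(as_traj_list(trajs), length, integer(1)))
}

as_traj_list <- function(trajs) {
  if (inherits(trajs, "trajectory")) return(list(trajs))
  if (is.list(trajs) && all(vapply(trajs, inherits, logical(1), "trajectory"))) {
    return(trajs)
  }
  stop("expected a trajectory or a list of trajectories", call. = FALSE)
}

# flatten trajectories into one frame list + bookkeeping tibble
flatten_frames <- function(trajs) {
  trajs <- as_traj_list(trajs)
  frames <- unlist(lapply(trajs, function(tr) tr$frames), recursive = FALSE)
  info <- tibble::tibble(
    trajectory_id = rep(
      vapply(trajs, function(tr) tr$trajectory_id, character(1)),
      vapply(trajs, length, integer(1))
    ),
    frame_index = unlist(lapply(trajs, function(tr) {
      vapply(tr$frames, function(f) f$frame_index, integer(1))
    }))
  )
  box <- trajs[[1]]$box
  list(frames = frames, info = info, box = box)
}

#' Atom selection rules for trajectory files
#'
#' Identifies which file atoms form the solute point set and which single atom
#' per solvent molecule (the water oxygen) forms the solvent point set. Each
#' selector is either an integer vector of 1-based atom indices (positions
#' within a frame) or a rule list with any of `elements`, `atom_names`,
#' `residues` (character vectors, matched case-insensitively). The PDB water
#' default picks atoms named O/OW in residues HOH/WAT/SOL/TIP3.
#'
#' @param solute solute selector (indices or rule list).
#' @param solvent solvent selector (indices or rule list); default matches
#'   standard water oxygen naming.
#' @return Object of class `selection_spec`.
#' @export
selection_spec <- function(solute,
                           solvent = list(atom_names = c("O", "OW"),
                                          residues = c("HOH", "WAT", "SOL", "TIP3"))) {
  structure(list(solute = solute, solvent = solvent), class = "selection_spec")
}

# resolve a selector against per-atom metadata for one frame
resolve_selector <- function(sel, atoms, what, frame) {
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    bad <- idx[idx < 1L | idx > nrow(atoms)]
    if (length(bad)) {
      stop(sprintf("selection error in frame %d: %s indices out of range (%s)",
                   frame, what, paste(bad, collapse = ", ")), call. = FALSE)
    }
    return(idx)
  }
  if (!is.list(sel)) stop("selector must be indices or a rule list", call. = FALSE)
  keep <- rep(TRUE, nrow(atoms))
  match_ci <- function(a, b) toupper(trimws(a)) %in% toupper(b)
  if (!is.null(sel$elements)) keep <- keep & match_ci(atoms$element, sel$elements)
  if (!is.null(sel$atom_names)) keep <- keep & match_ci(atoms$atom_name, sel$atom_names)
  if (!is.null(sel$residues)) keep <- keep & match_ci(atoms$residue, sel$residues)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop(sprintf("selection error in frame %d: no atoms match the %s selector",
                 frame, what), call. = FALSE)
  }
  idx
}

#' Read a multi-frame trajectory file
#'
#' Reads a multi-frame XYZ file (count line, comment line, `element x y z`
#' records, frames concatenated) or a multi-model PDB (MODEL/ENDMDL blocks;
#' parsed with \pkg{bio3d}) and applies an atom selection to produce one
#' [configuration()] per frame.
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; default guessed from the file extension.
#' @param selection a [selection_spec()].
#' @param lag_time frame interval (time units).
#' @param trajectory_id label; defaults to the file name.
#' @param box optional periodic box (see [trajectory()]).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("guess", "xyz", "pdb"), selection,
                            lag_time = 1, trajectory_id = NULL, box = NULL) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!inherits(selection, "selection_spec")) {
    stop("selection must be a selection_spec()", call. = FALSE)
  }
  raw <- switch(format, xyz = parse_xyz(path), pdb = parse_pdb(path))
  frames <- vector("list", length(raw))
  sol_idx0 <- NULL
  for (i in seq_along(raw)) {
    at <- raw[[i]]$atoms
    si <- resolve_selector(selection$solute, at, "solute", i)
    wi <- resolve_selector(selection$solvent, at, "solvent", i)
    if (length(intersect(si, wi))) {
      stop(sprintf("selection error in frame %d: solute and solvent selections overlap", i),
           call. = FALSE)
    }
    if (is.null(sol_idx0)) {
      sol_idx0 <- list(si, wi)
    } else if (!identical(sol_idx0, list(si, wi))) {
      stop(sprintf("selection error in frame %d: selected atom indices differ from frame 1", i),
           call. = FALSE)
    }
    frames[[i]] <- configuration(raw[[i]]$xyz[si, , drop = FALSE],
                                 raw[[i]]$xyz[wi, , drop = FALSE],
                                 frame_index = i)
  }
  trajectory(frames, lag_time = lag_time,
             trajectory_id = trajectory_id %||% basename(path), box = box)
}

parse_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  out <- list()
  pos <- 1L
  n_atoms0 <- NULL
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("XYZ format error at line %d: expected an atom count", pos), call. = FALSE)
    }
    if (pos + 1L + nat > length(lines)) {
      stop("XYZ format error: truncated final frame", call. = FALSE)
    }
    body <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(toks) < 4L)) {
      stop("XYZ format error: atom record with fewer than 4 fields", call. = FALSE)
    }
    elem <- vapply(toks, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(vapply(toks, function(t) t[2:4], character(3))),
                  ncol = 3L, byrow = TRUE)
    if (any(!is.finite(xyz))) stop("XYZ format error: non-numeric coordinate", call. = FALSE)
    if (is.null(n_atoms0)) {
      n_atoms0 <- nat
    } else if (nat != n_atoms0) {
      stop(sprintf("XYZ format error: frame %d has %d atoms, frame 1 has %d",
                   length(out) + 1L, nat, n_atoms0), call. = FALSE)
    }
    out[[length(out) + 1L]] <- list(
      atoms = tibble::tibble(element = elem, atom_name = elem,
                             residue = NA_character_),
      xyz = xyz
    )
    pos <- pos + 2L + nat
  }
  if (!length(out)) stop("XYZ file contains no frames", call. = FALSE)
  out
}

parse_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- tibble::tibble(
    element = ifelse(is.na(pdb$atom$elesy) | !nzchar(trimws(pdb$atom$elesy)),
                     substr(trimws(pdb$atom$elety), 1L, 1L),
                     trimws(pdb$atom$elesy)),
    atom_name = trimws(pdb$atom$elety),
    residue = trimws(pdb$atom$resid)
  )
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(i) {
    list(atoms = atoms,
         xyz = matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE))
  })
}

#' Write a trajectory to a multi-frame file
#'
#' Emits a multi-frame XYZ or multi-model PDB holding solute atoms first and
#' solvent positions after them, readable back by [read_trajectory()] with an
#' index-based selection (`selection_spec(solute = 1:m, solvent = m + 1:n)`).
#' In PDB output solute atoms are written as `ATOM` records (residue `MOL`,
#' element C) and solvent as `HETATM` oxygen records in residue `HOH`, so the
#' default water selection also works. Coordinates are printed with the
#' format's conventional precision (XYZ: 10 decimals; PDB: 3 decimals).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param format `"xyz"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  if (!inherits(traj, "trajectory") || length(traj$frames) == 0L) {
    stop("traj must be a non-empty trajectory", call. = FALSE)
  }
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  if (format == "xyz") write_xyz_frames(traj, con) else write_pdb_frames(traj, con)
  invisible(path)
}

write_xyz_frames <- function(traj, con) {
  for (f in traj$frames) {
    m <- nrow(f$solute); n <- nrow(f$solvent)
    writeLines(as.character(m + n), con)
    writeLines(sprintf("frame %d solute %d solvent %d", f$frame_index, m, n), con)
    xyz <- rbind(f$solute, f$solvent)
    elem <- c(rep("C", m), rep("O", n))
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                       elem, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
}

write_pdb_frames <- function(traj, con) {
  for (f in traj$frames) {
    m <- nrow(f$solute); n <- nrow(f$solvent)
    writeLines(sprintf("MODEL     %4d", f$frame_index), con)
    for (i in seq_len(m)) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, sprintf("C%d", i), "MOL", 1L,
        f$solute[i, 1], f$solute[i, 2], f$solute[i, 3], 1, 0, "C"), con)
    }
    for (j in seq_len(n)) {
      writeLines(sprintf(
        "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        m + j, "O", "HOH", 1L + j,
        f$solvent[j, 1], f$solvent[j, 2], f$solvent[j, 3], 1, 0, "O"), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

#' Convert a trajectory to a tidy coordinate table
#'
#' @param x a [trajectory()].
#' @param ... unused.
#' @return Tibble with one row per atom per frame: `trajectory_id`,
#'   `frame_index`, `role` (solute/solvent), `atom`, `x`, `y`, `z`.
#' @method tidy trajectory
#' @export
tidy.trajectory <- function(x, ...) {
  purrr::map_dfr(x$frames, function(f) {
    m <- nrow(f$solute); n <- nrow(f$solvent)
    xyz <- rbind(f$solute, f$solvent)
    tibble::tibble(
      trajectory_id = x$trajectory_id,
      frame_index = f$frame_index,
      role = rep(c("solute", "solvent"), c(m, n)),
      atom = c(seq_len(m), seq_len(n)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
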