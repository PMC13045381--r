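#' Write / read feature trajectories as a binary container
#'
#' A directory holding one flat binary array per trajectory (float64,
#' column-major) plus a JSON manifest recording dtype, shapes, frame
#' interval and feature names — a minimal language-neutral container for
#' feature matrices.
#'
#' @param trajs list of [feature_trajectory()] (or `latent_trajectory`;
#'   labels, when present, are written alongside as plain text and are not
#'   part of the feature data).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_features <- function(trajs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(trajs))
  shapes <- vector("list", length(trajs))
  fi <- NULL; fn <- NULL
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    vals <- if (!is.null(tr$values)) tr$values else tr$features
    files[i] <- sprintf("traj_%03d.bin", i)
    shapes[[i]] <- dim(vals)
    fi <- tr$frame_interval
    fn <- tr$feature_names
    con <- file(file.path(dir, files[i]), "wb")
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
    close(con)
    if (!is.null(tr$macrostate_labels)) {
      writeLines(as.character(tr$macrostate_labels),
                 file.path(dir, sprintf("traj_%03d.labels.txt", i)))
    }
  }
  manifest <- list(dtype = "float64", order = "column-major",
                   n_traj = length(trajs), files = files, shapes = shapes,
                   frame_interval = fi,
                   feature_names = fn %||% paste0("f", seq_len(shapes[[1]][2])))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_features
#' @param with_labels also read held-out per-frame label files when present.
#' @export
read_features <- function(dir, with_labels = FALSE) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- vector("list", manifest$n_traj)
  shapes <- manifest$shapes
  if (is.matrix(shapes)) shapes <- split(shapes, row(shapes))
  for (i in seq_len(manifest$n_traj)) {
    shp <- unlist(shapes[[i]])
    con <- file(file.path(dir, manifest$files[i]), "rb")
    v <- readBin(con, "double", n = prod(shp), size = 8, endian = "little")
    close(con)
    ft <- feature_trajectory(matrix(v, shp[1], shp[2]),
                             manifest$frame_interval,
                             manifest$feature_names)
    if (with_labels) {
      lf <- file.path(dir, sprintf("traj_%03d.labels.txt", i))
      if (file.exists(lf)) {
        attr(ft, "labels") <- as.integer(readLines(lf))
      }
    }
    out[[i]] <- ft
  }
  out
}

#' Read coordinate frames from a multi-model PDB
#'
#' Coordinates in Angstrom; residues are mapped to domain labels through a
#' user-supplied domain-range table. Residues not covered by the table are
#' labelled `"other"` with a warning.
#'
#' @param path PDB file (single- or multi-model; models must share the atom
#'   count).
#' @param domain_table data.frame with columns `name`, `start`, `end`
#'   (residue-id ranges); optional column `class` overrides the molecule
#'   class (defaults to `name`).
#' @param slab optional membrane slab passed to each frame.
#' @return list of [structure_frame()], one per model.
#' @export
read_pdb_frames <- function(path, domain_table, slab = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  n_atoms <- nrow(atoms)
  res <- atoms$resno
  dom <- rep(NA_character_, n_atoms)
  for (r in seq_len(nrow(domain_table))) {
    hit <- res >= domain_table$start[r] & res <= domain_table$end[r]
    dom[hit] <- domain_table$name[r]
  }
  if (anyNA(dom)) {
    warning(sprintf("read_pdb_frames: %d atoms outside the domain table labelled 'other'",
                    sum(is.na(dom))))
    dom[is.na(dom)] <- "other"
  }
  at <- data.frame(residue_id = res, residue_name = atoms$resid,
                   molecule_id = match(dom, unique(dom)),
                   molecule_class = dom)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * n_atoms) stop("read_pdb_frames: inconsistent models")
  lapply(seq_len(nrow(xyz)), function(m) {
    structure_frame(matrix(xyz[m, ], ncol = 3, byrow = TRUE), at, slab = slab)
  })
}

#' Write structure frames as a (multi-model) PDB
#'
#' @param frames `structure_frame` or list of them (same atoms).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(frames, path) {
  if (inherits(frames, "structure_frame")) frames <- list(frames)
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f$coords))))
  f1 <- frames[[1]]
  n <- nrow(f1$coords)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = f1$atoms$residue_id,
                   resid = substr(f1$atoms$residue_name, 1, 4),
                   chain = rep("A", n),
                   eleno = seq_len(n),
                   elety = rep("CA", n))
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML with one block per stage; every stochastic stage must carry an
#' explicit seed. See [pipeline_defaults()] for recognised fields.
#'
#' @param path YAML file.
#' @return named list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(pipeline_defaults(), cfg)
}

#' Default pipeline parameters
#'
#' Units: lags in frames, times in ns, distances in Angstrom.
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    fixture = "popc",
    time_scale = 1,
    n_traj = 50L,
    n_frames = 20000L,
    feature_dim = 5L,
    seed = 1L,
    traj_seeds = NULL,
    tica_lag = 5L,
    n_microstates = 50L,
    kmeans_fit_stride = 10L,
    n_macro = 4L,
    its_lags = c(1L, 2L, 3L, 5L, 8L, 12L, 20L),
    n_timescales = 3L,
    msm_lag = NULL,          # NULL: implied-timescale plateau rule
    bayes_samples = 100L,
    run_ck = FALSE,
    ck_factors = c(1L, 2L, 4L),
    output_dir = NULL
  )
}
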