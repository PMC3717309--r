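#' Default run configuration
#'
#' Collects every tunable constant of the pipeline in one plain structure;
#' all values are auditable defaults, nothing is hard-coded downstream.
#' Notable entries: the acquisition voxel pitch (120, 120, 250) nm, the K-L
#' dissimilarity threshold 4.5 bits, 64 histogram bins per axis, and the
#' 500 nm analysis cube.
#'
#' @param ... overrides for any top-level key; unknown keys are rejected
#'   with the offending key named.
#' @return config list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    input = NULL,              # TIFF path(s)
    channel_map = c(DAPI = 1, MeC = 2),
    voxel_size_nm = c(120, 120, 250),
    bit_depth = 12L,
    expected_radius_nm = 5000,
    min_volume_px = 50L,
    exclude_border = TRUE,
    kl_bins = 64L,
    kl_epsilon = 1e-6,         # sub-pixel pseudocount per bin
    kl_threshold = 4.5,
    cube_size_nm = 500,
    n_shells = 5L,
    scale_percentile = 0.995,
    out_dir = ".",
    sample_id = "sample",
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [defaultConfig()].
#' @return config list (defaults filled in; unknown keys rejected).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$channel_map)) y$channel_map <- unlist(y$channel_map)
  do.call(defaultConfig, y)
}

.writeProvenance <- function(config, counts, path) {
  prov <- list(
    package = "qdmi3d",
    version = as.character(utils::packageVersion("qdmi3d")),
    seed = config$seed,
    config = config[!vapply(config, is.null, TRUE)],
    counts = as.list(counts)
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Full per-stack analysis: segmentation, K-L filtering, TVA features
#'
#' Runs the whole single-stack pipeline on an in-memory
#' \linkS4class{ImageStack}: DAPI segmentation, MeC/DAPI codistribution
#' scoring with outlier flagging, and TVA feature extraction for every
#' retained nucleus.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param config a config list from [defaultConfig()].
#' @param labels optional precomputed label volume (skips segmentation;
#'   used e.g. to analyse ground-truth labels).
#' @return list with \code{cells} (per-nucleus feature data.frame
#'   including \code{kld} and \code{outlier_flag}), \code{rois},
#'   \code{labels}, \code{profiles} (per-kept-nucleus radial profiles) and
#'   \code{counts} (found / kept / border / small / kl-excluded; found =
#'   kept + excluded).
#' @export
analyzeStack <- function(stack, config = defaultConfig(), labels = NULL) {
  if (is.null(labels)) {
    seg <- segmentNuclei(stack,
                         expectedRadiusNm = config$expected_radius_nm,
                         minVolumePx = config$min_volume_px,
                         excludeBorder = config$exclude_border)
    rois <- seg$rois
    labels <- seg$labels
    excluded <- seg$excluded
  } else {
    rois <- collectRois(labels, minVolumePx = config$min_volume_px,
                        excludeBorder = config$exclude_border)
    excluded <- attr(rois, "excluded")
  }
  found <- length(rois) + sum(excluded)
  emptyCells <- data.frame(
    sample_id = character(), label = integer(), volume_px = integer(),
    mean_dapi = numeric(), mean_mec = numeric(), lid_pct = numeric(),
    lim_pct = numeric(), cond = numeric(), meth = numeric(),
    assoc = numeric(), kld = numeric(), outlier_flag = logical())
  if (length(rois) < 2L)
    return(list(cells = emptyCells, rois = rois, labels = labels,
                profiles = list(),
                counts = c(found = found, kept = length(rois),
                           border = unname(excluded["border"]),
                           small = unname(excluded["small"]),
                           kl = 0L)))

  dapi <- getChannel(stack, "DAPI")
  mec <- getChannel(stack, "MeC")
  dv <- lapply(rois, function(r) dapi[roiPixels(r)])
  mv <- lapply(rois, function(r) mec[roiPixels(r)])
  edge <- function(v) {
    r <- range(v)
    if (r[1L] == r[2L]) r[2L] <- r[1L] + 1
    seq(r[1L], r[2L] + 1e-9 * diff(r) + 1e-9,
        length.out = config$kl_bins + 1L)
  }
  edges <- list(dapi = edge(unlist(dv)), mec = edge(unlist(mv)))
  cods <- mapply(.jointHist, dv, mv, MoreArgs = list(binEdges = edges),
                 SIMPLIFY = FALSE)
  cods <- scoreKLD(cods, epsilon = config$kl_epsilon)
  fl <- flagOutliers(cods, threshold = config$kl_threshold)

  calib <- .calibrate(unlist(dv[fl$kept]), unlist(mv[fl$kept]),
                      2^stack@bitDepth - 1L, config$scale_percentile)
  rows <- vector("list", length(rois))
  profiles <- list()
  for (i in seq_along(rois)) {
    row <- .nucleusFeaturesVec(rois[[i]], stack, dv[[i]], mv[[i]], calib,
                               config$cube_size_nm, config$n_shells)
    prof <- attr(row, "profile")
    attr(row, "profile") <- NULL
    row$kld <- codKLD(cods[[i]])
    row$outlier_flag <- i %in% fl$dissimilar
    row <- cbind(sample_id = config$sample_id, row)
    rows[[i]] <- row
    if (!row$outlier_flag)
      profiles[[length(profiles) + 1L]] <- prof
  }
  cells <- do.call(rbind, rows)
  list(cells = cells, rois = rois, labels = labels, profiles = profiles,
       counts = c(found = found, kept = length(fl$kept),
                  border = unname(excluded["border"]),
                  small = unname(excluded["small"]),
                  kl = length(fl$dissimilar)))
}

#' Simulate a phantom field and write it to disk
#'
#' @param config config list ([defaultConfig()]); uses \code{out_dir},
#'   \code{voxel_size_nm}, \code{seed}, \code{sample_id}.
#' @param spec a [phenotypeSpec()].
#' @param nNuclei nuclei to place.
#' @param fieldShape stack shape \code{c(z, y, x)}.
#' @return invisibly, the population plus output paths. Writes
#'   \code{<sample>_stack.tif}, \code{<sample>_labels.tif},
#'   \code{<sample>_truth.csv} and a provenance JSON into \code{out_dir}.
#' @export
runSimulate <- function(config, spec, nNuclei, fieldShape) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- generatePopulation(nNuclei, spec, fieldShape,
                            voxelSize = config$voxel_size_nm,
                            seed = config$seed)
  base <- file.path(config$out_dir, config$sample_id)
  writeStack(pop$stack, paste0(base, "_stack.tif"))
  writeLabelVolume(pop$truth$labels, paste0(base, "_labels.tif"))
  writeCellTable(pop$truth$table, paste0(base, "_truth.csv"))
  .writeProvenance(config, c(nuclei = nrow(pop$truth$table)),
                   paste0(base, "_simulate_provenance.json"))
  invisible(list(pop = pop, paths = paste0(base, c("_stack.tif",
                                                   "_labels.tif",
                                                   "_truth.csv"))))
}

#' Segment a stack from disk and write labels + ROI table
#'
#' @param config config list; \code{input} must point at the TIFF.
#' @return invisibly, the segmentation result. Writes
#'   \code{<sample>_labels.tif}, \code{<sample>_rois.csv} and a
#'   provenance JSON.
#' @export
runSegment <- function(config) {
  stack <- readStack(config$input, channelMap = config$channel_map,
                     voxelSize = config$voxel_size_nm,
                     bitDepth = config$bit_depth)
  seg <- segmentNuclei(stack, expectedRadiusNm = config$expected_radius_nm,
                       minVolumePx = config$min_volume_px,
                       excludeBorder = config$exclude_border)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(config$out_dir, config$sample_id)
  writeLabelVolume(seg$labels, paste0(base, "_labels.tif"))
  roiTab <- do.call(rbind, lapply(seg$rois, function(r) data.frame(
    label = roiLabel(r), volume_px = roiVolume(r),
    centroid_z = roiCentroid(r)[1L], centroid_y = roiCentroid(r)[2L],
    centroid_x = roiCentroid(r)[3L])))
  if (is.null(roiTab))
    roiTab <- data.frame(label = integer(), volume_px = integer(),
                         centroid_z = numeric(), centroid_y = numeric(),
                         centroid_x = numeric())
  writeCellTable(roiTab, paste0(base, "_rois.csv"))
  .writeProvenance(config,
                   c(found = length(seg$rois) + sum(seg$excluded),
                     kept = length(seg$rois), seg$excluded),
                   paste0(base, "_segment_provenance.json"))
  invisible(seg)
}

#' Extract per-nucleus features from a stack on disk
#'
#' Full pipeline to the cell table: segmentation, K-L outlier flagging,
#' TVA features. Writes \code{<sample>_cells.csv} and a provenance JSON
#' whose counts satisfy found = kept + border + small + kl.
#'
#' @param config config list; \code{input} must point at the TIFF.
#' @return invisibly, the [analyzeStack()] result.
#' @export
runFeatures <- function(config) {
  stack <- readStack(config$input, channelMap = config$channel_map,
                     voxelSize = config$voxel_size_nm,
                     bitDepth = config$bit_depth)
  res <- analyzeStack(stack, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(config$out_dir, config$sample_id)
  writeCellTable(res$cells, paste0(base, "_cells.csv"))
  .writeProvenance(config, res$counts,
                   paste0(base, "_features_provenance.json"))
  invisible(res)
}

#' Population statistics over pooled cell tables
#'
#' Pools per-sample cell tables (outliers excluded), summarises each
#' sample, correlates sample-mean features against growth rate within each
#' cell class, and runs growth-response model selection per feature for
#' classes with enough samples.
#'
#' @param cellTables named list of per-nucleus data.frames (names =
#'   sample ids), as written by [runFeatures()].
#' @param metadata data.frame with columns \code{sample_id, cell_type,
#'   passage, doubling_time_days, condition}; \code{doubling_time_days}
#'   may be \code{Inf} for senescent samples. Column \code{class}
#'   (\code{"primary"} or \code{"cancer"}) groups the correlation analyses.
#' @param features features to correlate.
#' @param outDir optional directory: writes \code{summary.csv},
#'   \code{correlation.csv} and \code{fits.json}.
#' @return list with \code{summaries}, \code{sampleMeans},
#'   \code{correlations} (one row per class x feature: r, r2, n) and
#'   \code{fits} (per class x feature \code{FitResult} from
#'   [selectModel()], where >= 5 samples).
#' @export
runStats <- function(cellTables, metadata,
                     features = c("cond", "meth", "assoc"),
                     outDir = NULL) {
  stopifnot(all(names(cellTables) %in% metadata$sample_id))
  summaries <- list()
  meansRows <- list()
  for (sid in names(cellTables)) {
    cells <- cellTables[[sid]]
    cells <- cells[!cells$outlier_flag, , drop = FALSE]
    summaries[[sid]] <- summarizeSample(cells)
    md <- metadata[metadata$sample_id == sid, , drop = FALSE]
    row <- data.frame(sample_id = sid,
                      doubling_time_days = md$doubling_time_days[1L],
                      class = md$class[1L], n_cells = nrow(cells))
    for (f in features) row[[f]] <- mean(cells[[f]])
    meansRows[[sid]] <- row
  }
  sampleMeans <- do.call(rbind, meansRows)
  rownames(sampleMeans) <- NULL

  corRows <- list()
  fits <- list()
  for (cl in unique(sampleMeans$class)) {
    sub <- sampleMeans[sampleMeans$class == cl, , drop = FALSE]
    for (f in features) {
      if (nrow(sub) >= 3L) {
        pc <- tryCatch(pearsonVsGrowth(sub, f), error = function(e) NULL)
        if (!is.null(pc))
          corRows[[paste(cl, f)]] <- data.frame(
            class = cl, feature = f, r = pc$r, r2 = pc$r2, n = pc$n)
      }
      if (nrow(sub) >= 5L) {
        g <- growthRate(sub$doubling_time_days)
        fit <- tryCatch(selectModel(g, sub[[f]]), error = function(e) NULL)
        if (!is.null(fit)) fits[[paste(cl, f, sep = ".")]] <- fit
      }
    }
  }
  correlations <- if (length(corRows)) do.call(rbind, corRows) else
    data.frame(class = character(), feature = character(), r = numeric(),
               r2 = numeric(), n = integer())
  rownames(correlations) <- NULL

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sm <- do.call(rbind, lapply(names(summaries), function(sid)
      cbind(sample_id = sid, summaries[[sid]],
            n_cells = attr(summaries[[sid]], "nCells"))))
    writeCellTable(sm, file.path(outDir, "summary.csv"))
    writeCellTable(correlations, file.path(outDir, "correlation.csv"))
    jsonlite::write_json(
      lapply(fits, function(f) list(model = f$model, params = f$params,
                                    r2 = f$r2)),
      file.path(outDir, "fits.json"), auto_unbox = TRUE, digits = NA)
  }
  list(summaries = summaries, sampleMeans = sampleMeans,
       correlations = correlations, fits = fits)
}
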