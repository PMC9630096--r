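#' Load a delimited matrix with validation
#'
#' Reads whitespace/tab-delimited text. `"square_symmetric"` expects a
#' dense numeric matrix (optionally with matching row/column labels) and
#' enforces symmetry to 1e-8; `"regions_by_features"` expects a header row
#' of feature names and a first column of region labels. Ragged rows are an
#' error reporting the offending line; any non-finite cell is an error
#' naming its row and column.
#'
#' @param path file path.
#' @param expected `"square_symmetric"` or `"regions_by_features"`.
#' @return A list with `values` (numeric matrix), `rowLabels`,
#'   `colLabels`.
#' @export
loadMatrix <- function(path,
                       expected = c("square_symmetric",
                                    "regions_by_features")) {
  expected <- match.arg(expected)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(fields)

  if (expected == "regions_by_features") {
    if (any(lens[-1] != lens[2])) {
      stop("ragged row at line ", which(lens[-1] != lens[2])[1] + 1,
           call. = FALSE)
    }
    header <- fields[[1]]
    body <- fields[-1]
    rowLabels <- vapply(body, `[`, character(1), 1)
    vals <- t(vapply(body, function(f) suppressWarnings(as.numeric(f[-1])),
                     numeric(lens[2] - 1)))
    colLabels <- if (length(header) == lens[2]) header[-1] else header
    dimnames(vals) <- list(rowLabels, colLabels)
  } else {
    if (any(lens != lens[1])) {
      stop("ragged row at line ", which(lens != lens[1])[1], call. = FALSE)
    }
    first <- suppressWarnings(as.numeric(fields[[1]]))
    hasHeader <- anyNA(first)
    if (hasHeader) {
      header <- fields[[1]]
      body <- fields[-1]
      rowLabels <- vapply(body, `[`, character(1), 1)
      nCols <- lengths(body)[1] - 1
      # drop the row-label slot from the header when it carries one
      colLabels <- if (length(header) == nCols + 1) header[-1] else header
      vals <- t(vapply(body, function(f) suppressWarnings(as.numeric(f[-1])),
                       numeric(nCols)))
      dimnames(vals) <- list(rowLabels, colLabels)
    } else {
      vals <- t(vapply(fields, function(f) suppressWarnings(as.numeric(f)),
                       numeric(lens[1])))
      rowLabels <- colLabels <- NULL
    }
  }
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite value at row ",
         if (!is.null(rownames(vals))) rownames(vals)[bad[1, 1]]
         else bad[1, 1],
         ", column ",
         if (!is.null(colnames(vals))) colnames(vals)[bad[1, 2]]
         else bad[1, 2],
         call. = FALSE)
  }
  if (expected == "square_symmetric") {
    .checkSquareSymmetric(vals, basename(path))
  }
  message("loaded ", nrow(vals), " x ", ncol(vals), " matrix from ",
          basename(path))
  list(values = vals, rowLabels = rownames(vals), colLabels = colnames(vals))
}

#' Write a labelled matrix as TSV
#'
#' Values are written with 12 significant digits so a write-read round trip
#' reproduces them to ~1e-12 relative precision.
#'
#' @param x numeric matrix.
#' @param path output path.
#' @param rowLabelName header for the row-label column.
#' @export
writeMatrixTSV <- function(x, path, rowLabelName = "region_id") {
  rl <- rownames(x)
  if (is.null(rl)) rl <- as.character(seq_len(nrow(x)))
  cl <- colnames(x)
  if (is.null(cl)) cl <- paste0("V", seq_len(ncol(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(rowLabelName, cl), collapse = "\t"), con)
  body <- apply(format(x, digits = 12, scientific = TRUE, trim = TRUE), 1,
                paste, collapse = "\t")
  writeLines(paste(rl, body, sep = "\t"), con)
  invisible(path)
}

#' Write a dense connectome matrix (whitespace-delimited, no labels)
#' @param x symmetric numeric matrix.
#' @param path output path.
#' @export
writeConnectome <- function(x, path) {
  utils::write.table(format(x, digits = 12, scientific = TRUE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write parcel geometry as TSV
#'
#' Columns: region_id, hemisphere, centroid x/y/z (mm), sphere sx/sy/sz.
#' @param geometry a [ParcelGeometry-class].
#' @param path output path.
#' @export
writeGeometry <- function(geometry, path) {
  df <- data.frame(
    region_id = regionIds(geometry),
    hemisphere = hemispheres(geometry),
    centroids(geometry),
    sphereCoords(geometry)
  )
  colnames(df)[3:8] <- c("x", "y", "z", "sx", "sy", "sz")
  utils::write.table(format(df, digits = 12, trim = TRUE), path,
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read parcel geometry written by [writeGeometry()]
#' @param path geometry TSV path.
#' @return A [ParcelGeometry-class] (no medial-wall marker).
#' @export
readGeometry <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cent <- as.matrix(df[, c("x", "y", "z")])
  sph <- as.matrix(df[, c("sx", "sy", "sz")])
  sph <- sph / sqrt(rowSums(sph^2))
  rownames(cent) <- rownames(sph) <- df$region_id
  new("ParcelGeometry", regionIds = df$region_id, centroids = cent,
      sphereCoords = sph, hemisphere = df$hemisphere,
      medialWall = matrix(numeric(0), 0, 3),
      distance = as.matrix(stats::dist(cent)))
}

#' Run the full chemoarchitecture pipeline
#'
#' Chains the analysis stages on files referenced by a configuration (a
#' list or a YAML file): atlas assembly, receptor similarity, distance
#' decay, principal gradient, spin ensemble, rewiring nulls and the
#' connected-edge contrast (when a structural connectome is given),
#' receptor-augmented structure-function coupling (when both connectomes
#' are given), multilinear model + dominance + distance CV per target map,
#' and PLS against a term matrix. Stage outputs are written as TSVs under
#' `outDir` alongside a machine-readable JSON report; a missing optional
#' input skips its stage with a notice. Identical configuration and seed
#' reproduce the report byte for byte.
#'
#' @param config named list or path to a YAML file with entries:
#'   `geometry`, `atlas` (paths; required), optional `sc`, `fc`, `targets`,
#'   `terms` (paths), `nPerm` (default 1000), `nNulls` (default 100),
#'   `seed` (default 1), `trainFrac` (0.75), `fdrQ` (0.05), `outDir`.
#' @return The report, invisibly (also written to `outDir/report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(nPerm = 1000, nNulls = 100, seed = 1, trainFrac = 0.75,
                   fdrQ = 0.05, outDir = "chemoarch_out")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("geometry", "atlas")) {
    if (is.null(config[[nm]])) stop("config must provide '", nm, "'",
                                    call. = FALSE)
  }
  paths <- config[intersect(names(config),
                            c("geometry", "atlas", "sc", "fc", "targets",
                              "terms"))]
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) stop("missing input file for '", nm,
                                        "': ", paths[[nm]], call. = FALSE)
  }
  if (config$nPerm < 100) {
    warning("nPerm < 100: significance estimates will be coarse",
            call. = FALSE)
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "chemoarch", seed = config$seed,
                 nPerm = config$nPerm, stages = list())
  stamp <- function(stage, block, t0) {
    message(sprintf("[%s] done in %.1f s (seed %d)", stage,
                    as.numeric(Sys.time()) - t0, config$seed))
    report$stages[[stage]] <<- block
  }

  t0 <- as.numeric(Sys.time())
  geometry <- readGeometry(config$geometry)
  atl <- loadMatrix(config$atlas, "regions_by_features")
  meta <- data.frame(receptor = atl$colLabels,
                     row.names = atl$colLabels)
  atlas <- assembleAtlas(atl$values, meta)
  stamp("atlas", list(nRegions = nrow(atl$values),
                      nReceptors = ncol(atl$values)), t0)

  t0 <- as.numeric(Sys.time())
  sim <- receptorSimilarity(atlas)
  decay <- fitDistanceDecay(sim, geometry)
  grad <- principalGradient(atlas)
  writeMatrixTSV(sim, file.path(config$outDir, "similarity.tsv"))
  writeMatrixTSV(cbind(gradient = grad$gradient),
                 file.path(config$outDir, "gradient.tsv"))
  stamp("similarity", list(
    decay = list(amplitude = decay@amplitude, rate = decay@rate,
                 offset = decay@offset),
    pc1VarExplained = grad$varExplained[1]), t0)

  t0 <- as.numeric(Sys.time())
  spins <- buildSpinEnsemble(geometry, config$nPerm, seed = config$seed)
  stamp("nulls", list(nPerm = config$nPerm), t0)

  if (!is.null(config$sc)) {
    t0 <- as.numeric(Sys.time())
    sc <- loadMatrix(config$sc, "square_symmetric")$values
    ens <- rewirePreservingLength(sc, geometry, nNulls = config$nNulls,
                                  seed = config$seed)
    contrast <- connectedContrastTest(sim, sc, ens)
    block <- list(connectedContrast = list(statistic = contrast$statistic,
                                           p = contrast$p))
    if (!is.null(config$fc)) {
      fc <- loadMatrix(config$fc, "square_symmetric")$values
      comm <- communicability(sc)
      coupling <- augmentedCoupling(comm, fc, sim, spins, q = config$fdrQ)
      writeMatrixTSV(cbind(r2_base = coupling@r2Base,
                           r2_augmented = coupling@r2Augmented,
                           delta = coupling@delta,
                           p_spin = coupling@pSpin,
                           significant = as.numeric(coupling@significant)),
                     file.path(config$outDir, "coupling.tsv"))
      block$coupling <- list(
        meanDelta = mean(coupling@delta),
        nSignificant = sum(coupling@significant))
    } else {
      message("no functional connectome: structure-function coupling skipped")
    }
    stamp("structfunc", block, t0)
  } else {
    message("no structural connectome: connectome stages skipped")
  }

  if (!is.null(config$targets)) {
    t0 <- as.numeric(Sys.time())
    targets <- loadMatrix(config$targets, "regions_by_features")$values
    fits <- lapply(seq_len(ncol(targets)), function(k) {
      y <- targets[, k]
      sig <- spinModelSignificance(atlas, y, spins)
      dom <- dominance(atlas, y)
      cv <- distanceCV(atlas, y, geometry, trainFrac = config$trainFrac)
      list(r2adj = sig$observed, pSpin = sig$p,
           topReceptor = names(which.max(totalDominance(dom))),
           meanTestR = cv@meanTestR)
    })
    names(fits) <- colnames(targets)
    pAdj <- fdrCorrect(vapply(fits, `[[`, numeric(1), "pSpin"),
                       q = config$fdrQ)
    for (k in seq_along(fits)) fits[[k]]$pFdr <- pAdj$adjusted[k]
    stamp("multilinear", fits, t0)
  }

  if (!is.null(config$terms)) {
    t0 <- as.numeric(Sys.time())
    terms <- loadMatrix(config$terms, "regions_by_features")$values
    pls <- plsDecompose(atlas, terms)
    sig <- plsSignificance(atlas, terms, spins)
    writeMatrixTSV(cbind(x_score = pls@xScores[, 1],
                         y_score = pls@yScores[, 1]),
                   file.path(config$outDir, "pls_scores.tsv"))
    stamp("pls", list(covExplainedLV1 = covExplained(pls)[1],
                      pSpinLV1 = sig$p[[1]]), t0)
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(config$outDir, "report.json"))
  invisible(report)
}
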