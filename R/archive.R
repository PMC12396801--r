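#' Save a fitted cascade to a model archive directory
#'
#' The archive is plain text: \code{vocab.csv}, one weight CSV per stage
#' (token, coefficient; intercept as a reserved \code{(intercept)} row;
#' stage 2 has one coefficient column per one-vs-rest class) and
#' \code{hyperparams.yaml}.  \code{\link{load_cascade}} reproduces the
#' model bit for bit: predictions from a reloaded model equal those of the
#' original.
#'
#' @param model fitted \code{bleedr_cascade}.
#' @param dir archive directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
save_cascade <- function(model, dir) {
  stopifnot(inherits(model, "bleedr_cascade"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vocabulary(model$vocab, file.path(dir, "vocab.csv"))
  toks <- model$vocab$tokens
  wdf <- function(coef_vec) {
    data.frame(token = c("(intercept)", toks), coef = coef_vec)
  }
  utils::write.csv(wdf(model$stage1$coef),
                   file.path(dir, "stage1_weights.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  s2 <- data.frame(token = c("(intercept)", toks))
  for (cl in model$stage2$classes) {
    f <- model$stage2$fits[[cl]]
    s2[[cl]] <- c(f$b, f$w)
  }
  utils::write.csv(s2, file.path(dir, "stage2_weights.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(wdf(model$stage3$coef),
                   file.path(dir, "stage3_weights.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  yaml::write_yaml(list(
    grid = model$hyperparams$grid,
    cv_folds = model$hyperparams$cv_folds,
    class_weighting = model$hyperparams$class_weighting,
    min_df = model$hyperparams$min_df,
    seed = model$seed,
    selected_C = list(stage1 = model$stage1$C, stage2 = model$stage2$C,
                      stage3 = model$stage3$C),
    stage2_classes = model$stage2$classes),
    file.path(dir, "hyperparams.yaml"))
  invisible(dir)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(dir) {
  hp_file <- file.path(dir, "hyperparams.yaml")
  if (!file.exists(hp_file)) stop("not a model archive: ", dir,
                                  call. = FALSE)
  meta <- yaml::read_yaml(hp_file)
  vocab <- read_vocabulary(file.path(dir, "vocab.csv"),
                           min_df = meta$min_df)
  read_w <- function(name) {
    df <- utils::read.csv(file.path(dir, name), stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    df
  }
  s1 <- read_w("stage1_weights.csv")
  s2 <- read_w("stage2_weights.csv")
  s3 <- read_w("stage3_weights.csv")
  classes <- unlist(meta$stage2_classes)
  fits <- lapply(classes, function(cl) {
    list(w = s2[[cl]][-1], b = s2[[cl]][1])
  })
  names(fits) <- classes
  structure(list(
    vocab = vocab,
    stage1 = list(coef = s1$coef, C = meta$selected_C$stage1),
    stage2 = list(fits = fits, classes = classes,
                  C = meta$selected_C$stage2),
    stage3 = list(coef = s3$coef, C = meta$selected_C$stage3),
    hyperparams = cascade_hyperparams(grid = unlist(meta$grid),
                                      cv_folds = meta$cv_folds,
                                      class_weighting = meta$class_weighting,
                                      min_df = meta$min_df),
    seed = meta$seed,
    train_report = NULL),
    class = "bleedr_cascade")
}

#' Write a run manifest into an output directory
#'
#' Records the resolved configuration, the seed and MD5 checksums of the
#' input files, sufficient to re-run the step bit-identically.
#'
#' @param dir output directory.
#' @param config named list of resolved parameters.
#' @param seed integer seed used.
#' @param inputs character vector of input file paths to checksum.
#' @return path to the manifest, invisibly.
#' @export
write_manifest <- function(dir, config, seed, inputs = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sums <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else list()
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(config = config, seed = seed,
                        input_md5 = sums), path)
  invisible(path)
}
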