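## End-to-end orchestration: preprocess -> discovery -> differential
## expression -> target prediction -> degradome, with per-stage TSV
## outputs, a JSON run manifest and a log. All randomness flows from one
## root seed expanded per stage.

.defaultPipelineParams <- function() {
  list(seed = 1L,
       preprocess = list(adapter = "TGGAATTCTCGGGTGCCAAGG", minLen = 18L,
                         maxLen = 30L, minQual = 20, maxHits = 20L),
       discovery = list(mfeThreshold = -30, flankMax = 280L),
       de = list(minRpm = 1, fold = 2, alpha = 0.01),
       targets = list(scoreCutoff = 2.5),
       degradome = list(scoreCutoff = 4, anchor = 20L, nShuffles = 100L,
                        medianOver = "detected"))
}

#' Read a pipeline configuration YAML
#'
#' The YAML has an \code{inputs} block (paths: genome, transcripts,
#' annotation, control, drought, degradome, optional known) plus
#' optional per-stage parameter blocks (\code{preprocess},
#' \code{discovery}, \code{de}, \code{targets}, \code{degradome}) and a
#' \code{seed}; unset parameters take the package defaults.
#'
#' @param path YAML path.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- .defaultPipelineParams()
  for (blk in names(defaults)) {
    if (blk == "seed") next
    user <- if (is.null(cfg[[blk]])) list() else cfg[[blk]]
    bad <- setdiff(names(user), names(defaults[[blk]]))
    if (length(bad))
      stop("unknown parameter(s) in '", blk, "' block: ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], user)
  }
  if (is.null(cfg$seed)) cfg$seed <- defaults$seed
  required <- c("genome", "transcripts", "annotation", "control",
                "drought", "degradome")
  missing <- setdiff(required, names(cfg$inputs))
  if (length(missing))
    stop("config inputs block lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cfg
}

.stage <- function(name, expr, log) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  cat(sprintf("[%s] stage %s done in %.1fs\n",
              format(Sys.time(), "%H:%M:%S"), name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = log, append = TRUE)
  res
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, discovery, differential expression, target
#' prediction and degradome confirmation over the configured inputs and
#' writes per-stage TSVs, a log, and a JSON run manifest. Reruns with an
#' identical config and seed reproduce every output byte.
#'
#' @param config a config list (see \code{\link{readPipelineConfig}}) or
#'   the path to a YAML config.
#' @param outdir output directory.
#' @return the manifest (a list), invisibly also written to
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  missing <- !vapply(unlist(config$inputs), file.exists, logical(1))
  if (any(missing))
    stop("missing input file(s): ",
         paste(unlist(config$inputs)[missing], collapse = ", "),
         call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outdir, "pipeline.log")
  cat("", file = log)
  pp <- config$preprocess
  stages <- character(0)

  ## 1: preprocess
  tags <- .stage("preprocess", {
    ctrl <- cleanAndCollapse(config$inputs$control, pp$adapter, pp$minLen,
                             pp$maxLen, pp$minQual)
    drt <- cleanAndCollapse(config$inputs$drought, pp$adapter, pp$minLen,
                            pp$maxLen, pp$minQual)
    tags <- TagSet(ctrl, drt)
    tags <- mapTags(tags, config$inputs$genome, maxHits = pp$maxHits)
    known <- if (!is.null(config$inputs$known)) config$inputs$known else
      character(0)
    tags <- annotateTags(tags, config$inputs$annotation, known)
    tags <- sirnaDuplexScan(tags)$tags
    tags
  }, log)
  stages <- c(stages, "preprocess")
  writeTagFasta(tags, file.path(outdir, "tags.fa"))
  write.table(lengthStats(tags), file.path(outdir, "length_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## 2: discovery
  disc <- .stage("discovery", {
    discoverNovelMirnas(tags, config$inputs$genome,
                        mfeThreshold = config$discovery$mfeThreshold,
                        flankMax = config$discovery$flankMax)
  }, log)
  stages <- c(stages, "discovery")
  write.table(disc$novel, file.path(outdir, "novel_mirnas.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(disc$rejections, file.path(outdir, "rejections.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## 3: differential expression over novel matures and known-miRNA tags
  de <- .stage("de", {
    N1 <- sum(tags@countControl)
    N2 <- sum(tags@countDrought)
    knownIdx <- which(tags@annotation == "known_mirna")
    records <- rbind(
      if (nrow(disc$novel)) data.frame(name = disc$novel$name,
                                       x = disc$novel$countControl,
                                       y = disc$novel$countDrought) else NULL,
      if (length(knownIdx)) data.frame(
        name = paste0("known_", seq_along(knownIdx)),
        x = tags@countControl[knownIdx],
        y = tags@countDrought[knownIdx]) else NULL)
    if (is.null(records) || !nrow(records))
      callDE(data.frame(name = character(0), x = integer(0),
                        y = integer(0)), max(N1, 1L), max(N2, 1L)) else
      callDE(records, N1, N2, minRpm = config$de$minRpm,
             fold = config$de$fold, alpha = config$de$alpha)
  }, log)
  stages <- c(stages, "de")
  write.table(de, file.path(outdir, "differential_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## 4: target prediction for the discovered miRNAs
  mirnas <- if (nrow(disc$novel))
    setNames(disc$novel$sequence, disc$novel$name) else character(0)
  mirnas <- mirnas[!duplicated(names(mirnas))]
  targetScan <- .stage("targets", {
    if (length(mirnas))
      scanTargets(mirnas, config$inputs$transcripts,
                  scoreCutoff = config$targets$scoreCutoff) else
      list(sites = data.frame(), alignments = list())
  }, log)
  stages <- c(stages, "targets")
  write.table(targetScan$sites, file.path(outdir, "predicted_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## 5: degradome confirmation
  events <- .stage("degradome", {
    profiles <- mapDegradome(config$inputs$degradome,
                             config$inputs$transcripts,
                             anchor = config$degradome$anchor)
    if (length(mirnas))
      runDegradome(mirnas, config$inputs$transcripts, profiles,
                   scoreCutoff = config$degradome$scoreCutoff,
                   nShuffles = config$degradome$nShuffles,
                   seed = .deriveSeed(config$seed, 50L),
                   medianOver = config$degradome$medianOver) else
      runDegradome(character(0), config$inputs$transcripts, profiles)
  }, log)
  stages <- c(stages, "degradome")
  write.table(events, file.path(outdir, "cleavage_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "mirpare",
    version = as.character(utils::packageVersion("mirpare")),
    seed = config$seed,
    parameters = config[c("preprocess", "discovery", "de", "targets",
                          "degradome")],
    inputs = lapply(config$inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = stages,
    outputs = list(tags = "tags.fa", lengthStats = "length_stats.tsv",
                   novel = "novel_mirnas.tsv", rejections = "rejections.tsv",
                   de = "differential_expression.tsv",
                   targets = "predicted_targets.tsv",
                   events = "cleavage_events.tsv"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' @param outdir the pipeline output directory (containing
#'   manifest.json).
#' @return list of headline counts: tags, known and novel miRNAs, novel
#'   families, DE calls by direction, cleavage events by category. Also
#'   writes \code{summary.tsv} next to the manifest.
#' @export
reportSummary <- function(outdir) {
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                                  simplifyVector = TRUE)
  tags <- readTagFasta(file.path(outdir, manifest$outputs$tags))
  novel <- read.delim(file.path(outdir, manifest$outputs$novel))
  de <- read.delim(file.path(outdir, manifest$outputs$de))
  events <- read.delim(file.path(outdir, manifest$outputs$events))
  summary <- list(
    uniqueTags = length(tags),
    totalReadsControl = sum(tagCounts(tags)[, "control"]),
    totalReadsDrought = sum(tagCounts(tags)[, "drought"]),
    novelMirnas = nrow(novel),
    novelFamilies = length(unique(novel$sequence)),
    deUp = sum(de$call == "up"),
    deDown = sum(de$call == "down"),
    eventsCategoryI = sum(events$category == "I"),
    eventsCategoryII = sum(events$category == "II"),
    eventsCategoryIII = sum(events$category == "III"))
  tab <- data.frame(metric = names(summary),
                    value = unlist(summary, use.names = FALSE))
  write.table(tab, file.path(outdir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary
}
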