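## Staged filtration funnel: per-study MR with the sensitivity battery,
## cross-study meta-analysis with FDR, colocalization, and validation
## (MR-PRESSO, cis+trans instruments, external replication).

#' Funnel run configuration
#'
#' Thresholds and stage toggles of the target-prioritization funnel. The
#' stage order is fixed: (1) per-study MR with sensitivity exclusions
#' (Egger intercept p < eggerAlpha, Cochran Q p < hetAlpha, Steiger FALSE),
#' (2) random-effects meta-analysis with BH FDR (keep q <= fdrAlpha),
#' (3) colocalization above \code{colocThreshold} (criterion \code{"h4"} =
#' PP.H4, or \code{"regional"} = PP.H3 + PP.H4 -- both conventions are in
#' use), (4) validation: MR-PRESSO (fail when the global test is significant
#' with at least one flagged outlier), replication with cis+trans
#' instruments, and replication in an external study. Each criterion can be
#' disabled individually; disabling a stage can only enlarge the final
#' target set.
#'
#' @param instrument an [instrumentConfig()].
#' @param fdrAlpha FDR level of stage 2 (default 0.05).
#' @param eggerAlpha,hetAlpha,pressoAlpha sensitivity test levels (0.05).
#' @param colocCriterion \code{"h4"} or \code{"regional"}.
#' @param colocThreshold posterior threshold (default 0.7, strictly greater).
#' @param pressoNSim MR-PRESSO simulation count (default 1000).
#' @param checkSensitivity,checkFdr,checkColoc,checkValidation stage toggles.
#' @param seed integer seed recorded in the report and driving MR-PRESSO.
#' @return list of class \code{"FunnelConfig"}.
#' @export
funnelConfig <- function(instrument = instrumentConfig(), fdrAlpha = 0.05,
                         eggerAlpha = 0.05, hetAlpha = 0.05,
                         pressoAlpha = 0.05,
                         colocCriterion = c("h4", "regional"),
                         colocThreshold = 0.7, pressoNSim = 1000L,
                         checkSensitivity = TRUE, checkFdr = TRUE,
                         checkColoc = TRUE, checkValidation = TRUE,
                         seed = 1L) {
  colocCriterion <- match.arg(colocCriterion)
  structure(list(instrument = instrument, fdrAlpha = fdrAlpha,
                 eggerAlpha = eggerAlpha, hetAlpha = hetAlpha,
                 pressoAlpha = pressoAlpha, colocCriterion = colocCriterion,
                 colocThreshold = colocThreshold,
                 pressoNSim = as.integer(pressoNSim),
                 checkSensitivity = checkSensitivity, checkFdr = checkFdr,
                 checkColoc = checkColoc, checkValidation = checkValidation,
                 seed = as.integer(seed)),
            class = "FunnelConfig")
}

## Instruments of one study as a SumStats subset; NULL when none survive.
.instrument_table <- function(study, locus, ld, icfg, mode = NULL) {
  cfg <- icfg
  if (!is.null(mode)) cfg$mode <- mode
  inst <- buildInstruments(study, locus, ld, cfg)
  if (nrow(inst) == 0) return(NULL)
  d <- study@data
  SumStats(d[d$snp %in% inst$snp, , drop = FALSE], traitId = study@traitId,
           traitType = study@traitType)
}

.study_mr <- function(study, outcome, locus, ld, cfg, seed, mode = NULL) {
  it <- .instrument_table(study, locus, ld, cfg$instrument, mode)
  if (is.null(it)) return(NULL)
  h <- harmonize(it, outcome)
  if (nrow(harmonizedPairs(h)) == 0) return(NULL)
  runMR(h, exposureId = study@traitId, outcomeId = outcome@traitId,
        pressoNSim = cfg$pressoNSim, seed = seed)
}

#' Run the target-prioritization funnel
#'
#' Applies the staged filtration of candidate targets: per-study MR with
#' sensitivity exclusions, cross-study random-effects meta-analysis with BH
#' FDR, colocalization with the outcome, and validation by MR-PRESSO,
#' cis+trans instruments and an external study. Targets dropped at any stage
#' are recorded with a reason code; stage record counts chain (the output
#' count of each stage is the input count of the next). Deterministic given
#' \code{config$seed}.
#'
#' @param targets named list of per-target inputs, each a list with elements
#'   \code{id}, \code{locus} ([GeneLocus-class]), \code{ld}
#'   ([LDMatrix-class]), \code{studies} (list of exposure
#'   [SumStats-class]), \code{external} (validation exposure table or NULL)
#'   and \code{outcome} ([SumStats-class]); exactly the shape produced by
#'   [simulateFunnelFixture()]\code{$targets}.
#' @param config a [funnelConfig()].
#' @return A [FunnelReport-class].
#' @export
runFunnel <- function(targets, config = funnelConfig()) {
  stopifnot(inherits(config, "FunnelConfig"))
  removed <- data.frame(target = character(0), stage = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  drop <- function(id, stage, reason)
    removed <<- rbind(removed, data.frame(target = id, stage = stage,
                                          reason = reason,
                                          stringsAsFactors = FALSE))
  details <- list()
  ids <- names(targets)
  if (is.null(ids)) ids <- vapply(targets, `[[`, character(1), "id")
  stage_counts <- list()

  ## ---- stage 1: per-study MR + sensitivity exclusions -------------------
  n_in <- length(targets)
  alive <- character(0)
  per_target <- list()
  for (i in seq_along(targets)) {
    tg <- targets[[i]]
    id <- ids[i]
    mrs <- list()
    for (j in seq_along(tg$studies)) {
      mr <- .study_mr(tg$studies[[j]], tg$outcome, tg$locus, tg$ld, config,
                      seed = config$seed * 10000L + i * 100L + j)
      if (!is.null(mr)) mrs[[length(mrs) + 1L]] <- mr
    }
    if (length(mrs) == 0) { drop(id, "mr_sensitivity", "no_instruments"); next }
    if (config$checkSensitivity) {
      pass <- vapply(mrs, function(m) {
        if (!is.na(m@eggerInterceptPval) &&
            m@eggerInterceptPval < config$eggerAlpha) return(FALSE)
        if (!is.na(m@qPval) && m@qPval < config$hetAlpha) return(FALSE)
        if (!is.na(m@steigerCorrect) && !m@steigerCorrect) return(FALSE)
        TRUE
      }, logical(1))
      if (!any(pass)) {
        drop(id, "mr_sensitivity", "pleiotropy_heterogeneity_or_direction")
        next
      }
      mrs <- mrs[pass]
    }
    per_target[[id]] <- list(target = tg, mrs = mrs)
    alive <- c(alive, id)
  }
  stage_counts$mr_sensitivity <- c(n_in, length(alive))

  ## ---- stage 2: meta-analysis + FDR -------------------------------------
  n_in <- length(alive)
  if (length(alive)) {
    metas <- lapply(alive, function(id) {
      mrs <- per_target[[id]]$mrs
      dlMeta(vapply(mrs, function(m) m@beta, numeric(1)),
             vapply(mrs, function(m) m@se, numeric(1)), targetId = id)
    })
    names(metas) <- alive
    f <- bhFdr(vapply(metas, function(m) m@pval, numeric(1)),
               config$fdrAlpha)
    for (j in seq_along(alive)) {
      metas[[j]]@fdrQ <- f$q_values[j]
      per_target[[alive[j]]]$meta <- metas[[j]]
    }
    if (config$checkFdr) {
      fail <- alive[!f$significant]
      for (id in fail) drop(id, "meta_fdr", "fdr_not_significant")
      alive <- alive[f$significant]
    }
  }
  stage_counts$meta_fdr <- c(n_in, length(alive))

  ## ---- stage 3: colocalization -------------------------------------------
  n_in <- length(alive)
  survivors <- character(0)
  for (id in alive) {
    tg <- per_target[[id]]$target
    coloc <- colocAbf(tg$studies[[1]], tg$outcome,
                      threshold = config$colocThreshold)
    per_target[[id]]$coloc <- coloc
    crit <- if (config$colocCriterion == "h4") unname(coloc@pp["H4"])
            else regionalProbability(coloc)
    if (config$checkColoc && !(crit > config$colocThreshold)) {
      drop(id, "colocalization",
           sprintf("%s_below_threshold", config$colocCriterion))
    } else survivors <- c(survivors, id)
  }
  alive <- survivors
  stage_counts$colocalization <- c(n_in, length(alive))

  ## ---- stage 4: validation ------------------------------------------------
  n_in <- length(alive)
  survivors <- character(0)
  for (id in alive) {
    entry <- per_target[[id]]
    tg <- entry$target
    primary <- entry$mrs[[1]]
    fail_reason <- NULL

    if (config$checkValidation) {
      if (!is.na(primary@pressoGlobalPval) &&
          primary@pressoGlobalPval < config$pressoAlpha &&
          length(primary@pressoOutliers) > 0)
        fail_reason <- "presso_pleiotropy"

      if (is.null(fail_reason)) {
        ct <- .study_mr(tg$studies[[1]], tg$outcome, tg$locus, tg$ld, config,
                        seed = config$seed * 10000L + 7L,
                        mode = "cis_and_trans")
        if (is.null(ct) || !replicationCheck(primary, ct))
          fail_reason <- "cis_trans_not_replicated"
        else per_target[[id]]$cisTrans <- ct
      }
      if (is.null(fail_reason) && !is.null(tg$external)) {
        ext <- .study_mr(tg$external, tg$outcome, tg$locus, tg$ld, config,
                         seed = config$seed * 10000L + 8L)
        if (is.null(ext) || !replicationCheck(primary, ext))
          fail_reason <- "external_not_replicated"
        else per_target[[id]]$external <- ext
      }
    }
    if (is.null(fail_reason)) survivors <- c(survivors, id)
    else drop(id, "validation", fail_reason)
  }
  alive <- survivors
  stage_counts$validation <- c(n_in, length(alive))

  stages <- data.frame(stage = names(stage_counts),
                       n_in = vapply(stage_counts, `[`, numeric(1), 1),
                       n_out = vapply(stage_counts, `[`, numeric(1), 2),
                       stringsAsFactors = FALSE)
  rownames(stages) <- NULL
  methods::new("FunnelReport", stages = stages, removed = removed,
               finalTargets = alive,
               details = per_target[alive], seed = config$seed)
}

#' Write a funnel report to disk
#'
#' \code{tsv} writes three tables: per-stage counts, removed targets with
#' reason codes, and the final targets with their pooled estimate,
#' colocalization summary and replication flags (columns mirroring how such
#' results are tabulated: effect, SE, p, q, PP.H4, top coloc variant).
#' \code{json} writes a single machine-readable summary. \code{"both"}
#' writes all files.
#'
#' @param report a [FunnelReport-class].
#' @param dir output directory (created if needed).
#' @param format \code{"tsv"}, \code{"json"} or \code{"both"}.
#' @return character vector of written paths, invisibly.
#' @export
renderReport <- function(report, dir, format = c("tsv", "json", "both")) {
  stopifnot(is(report, "FunnelReport"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  final_tab <- if (length(report@finalTargets)) {
    do.call(rbind, lapply(report@finalTargets, function(id) {
      d <- report@details[[id]]
      data.frame(target = id, k_studies = d$meta@kStudies,
                 beta = d$meta@beta, se = d$meta@se, pval = d$meta@pval,
                 fdr_q = d$meta@fdrQ,
                 pp_h4 = unname(d$coloc@pp["H4"]),
                 pp_regional = regionalProbability(d$coloc),
                 coloc_snp = d$coloc@topSharedVariant,
                 steiger = d$mrs[[1]]@steigerCorrect,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(target = character(0))

  if (format %in% c("tsv", "both")) {
    ptab <- function(x, name) {
      p <- file.path(dir, name)
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    paths <- c(paths, ptab(report@stages, "funnel_stages.tsv"),
               ptab(report@removed, "funnel_removed.tsv"),
               ptab(final_tab, "final_targets.tsv"))
  }
  if (format %in% c("json", "both")) {
    p <- file.path(dir, "funnel_summary.json")
    jsonlite::write_json(list(seed = report@seed,
                              stages = report@stages,
                              removed = report@removed,
                              final_targets = report@finalTargets),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
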