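plate_cols <- c("well", "condition", "monomer_uM", "seed_nM", "compound",
                "compound_uM", "replicate", "time_s", "fluorescence")

#' Read a plate-reader long table into kinetic traces
#'
#' Expects a comma-separated UTF-8 file with header
#' `well,condition,monomer_uM,seed_nM,compound,compound_uM,replicate,time_s,fluorescence`;
#' `#`-prefixed comment lines are permitted. Rows are grouped by well,
#' sorted by time, and returned as [kinetic_trace()]s with the condition
#' labels in `meta`.
#'
#' @param path File path.
#' @return Named list of `kinetic_trace` (names = well ids); empty data
#'   section gives an empty list.
#' @export
read_plate_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing <- setdiff(plate_cols, names(df))
  if (length(missing)) {
    stop("plate table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  out <- lapply(split(df, df$well), function(w) {
    w <- w[order(w$time_s), ]
    dup <- duplicated(w$time_s)
    if (any(dup)) {
      stop("duplicate (well, time) rows for well ", w$well[1], " at row(s) ",
           paste(which(dup), collapse = ", "))
    }
    kinetic_trace(w$time_s, w$fluorescence,
                  meta = list(well = w$well[1], condition = w$condition[1],
                              monomer_uM = w$monomer_uM[1],
                              seed_nM = w$seed_nM[1],
                              compound = w$compound[1],
                              compound_uM = w$compound_uM[1],
                              replicate = w$replicate[1]))
  })
  out[order(names(out))]
}

#' Write kinetic traces as a plate-reader long table
#'
#' @param traces List of [kinetic_trace()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    m <- tr$meta
    gv <- function(f, d) if (!is.null(m[[f]])) m[[f]] else d
    data.frame(well = gv("well", i),
               condition = gv("condition",
                              paste0(gv("compound", "none"), "_",
                                     gv("monomer_uM", NA))),
               monomer_uM = gv("monomer_uM", NA),
               seed_nM = gv("seed_nM", NA),
               compound = gv("compound", "none"),
               compound_uM = gv("compound_uM", 0),
               replicate = gv("replicate", 1),
               time_s = tr$time, fluorescence = tr$signal)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a SMILES library (`id<TAB>smiles` or delimited with header)
#'
#' @param path File path. Tab-separated two-column files without header
#'   and comma-separated files with `id`/`smiles` header are accepted.
#' @return data.frame with columns `id`, `smiles`.
#' @export
read_library <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("id", first) && grepl(",", first)) {
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    df[, c("id", "smiles")]
  } else {
    df <- utils::read.table(path, sep = "\t", col.names = c("id", "smiles"),
                            comment.char = "#", stringsAsFactors = FALSE)
    df
  }
}

#' Write a SMILES library as `id<TAB>smiles`
#' @param library_df data.frame with `id`, `smiles`.
#' @param path Output path.
#' @export
write_library <- function(library_df, path) {
  utils::write.table(library_df[, c("id", "smiles")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a binding titration table (`compound,fibril_uM,delta_mP,sd`)
#' @param path File path.
#' @return A [binding_titration()].
#' @export
read_titration <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  binding_titration(df$compound[1], df$fibril_uM * 1e-6, df$delta_mP,
                    sd = if ("sd" %in% names(df)) df$sd else NULL)
}

#' @rdname read_titration
#' @param titration A [binding_titration()].
#' @export
write_titration <- function(titration, path) {
  utils::write.csv(data.frame(compound = titration$compound_id,
                              fibril_uM = titration$fibril_concs * 1e6,
                              delta_mP = titration$delta_mP,
                              sd = if (is.null(titration$sd)) NA
                                   else titration$sd),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summary report of a screening run
#'
#' Combines campaign history, mechanism reports and binding fits into one
#' machine-readable record and one human-readable table: the
#' per-iteration hit-rate table and the top-10 compounds by normalized
#' half-time. Partial inputs produce partial reports with explicit gaps.
#'
#' @param campaign A `campaign_state`, or NULL.
#' @param mechanism List of `mechanism_report`s, or NULL.
#' @param binding List of binding-fit results (from
#'   [fit_one_site_binding()]), or NULL.
#' @param kic50_fits Named list of [kic50()] results, or NULL.
#' @param path Optional path prefix; writes `<path>.json` and
#'   `<path>_top10.csv`.
#' @return List with `json` (the report record) and `top10` (data.frame).
#' @export
report <- function(campaign = NULL, mechanism = NULL, binding = NULL,
                   kic50_fits = NULL, path = NULL) {
  rec <- list(gaps = character(0))
  top10 <- data.frame(id = character(0), t12_norm = numeric(0))
  if (!is.null(campaign)) {
    rec$iterations <- campaign$history
    ord <- order(-campaign$tested$measured_t12_norm, campaign$tested$id)
    top10 <- data.frame(
      id = campaign$tested$id[ord],
      t12_norm = campaign$tested$measured_t12_norm[ord],
      iteration = campaign$tested$iteration_tested[ord])[
        seq_len(min(10, nrow(campaign$tested))), ]
    rec$top10 <- top10
  } else rec$gaps <- c(rec$gaps, "campaign")
  if (!is.null(mechanism)) {
    rec$mechanism <- lapply(mechanism, function(m)
      list(compound = m$compound_id, delta_k2 = m$delta_k2,
           delta_kplus = m$delta_kplus))
  } else rec$gaps <- c(rec$gaps, "mechanism")
  if (!is.null(binding)) {
    rec$binding <- lapply(binding, function(b)
      list(K_D_uM = b$K_D * 1e6, K_D_sd_uM = b$K_D_sd * 1e6,
           B_max_mP = b$B_max, poorly_determined = b$poorly_determined))
  } else rec$gaps <- c(rec$gaps, "binding")
  if (!is.null(kic50_fits)) {
    rec$kic50 <- lapply(kic50_fits, function(k)
      list(kic50_uM = k$kic50 * 1e6, flag = k$flag))
  } else rec$gaps <- c(rec$gaps, "kic50")
  if (!is.null(path)) {
    jsonlite::write_json(rec, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    utils::write.csv(top10, paste0(path, "_top10.csv"), row.names = FALSE)
  }
  list(json = rec, top10 = top10)
}

#' Run manifest
#'
#' Records everything needed to re-run an invocation bit-identically:
#' the configuration, input-file digests, package version, RNG seeds and
#' output paths.
#'
#' @param config List or `generator_config` snapshot.
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @param seeds Named numeric vector of RNG seeds used.
#' @param outputs Character vector of output paths.
#' @param path Optional path to write the manifest JSON.
#' @return The manifest list.
#' @export
run_manifest <- function(config = list(), inputs = character(0),
                         seeds = c(seed = NA_real_),
                         outputs = character(0), path = NULL) {
  digest1 <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    # content digest without extra deps: size + sum of bytes
    b <- readBin(f, "raw", file.info(f)$size)
    sprintf("%d:%.0f", length(b), sum(as.integer(b)))
  }
  man <- list(config = unclass(config),
              inputs = stats::setNames(vapply(inputs, digest1,
                                              character(1)), inputs),
              version = as.character(utils::packageVersion("seedkin")),
              seeds = as.list(seeds),
              timestamp = format(Sys.time(), tz = "UTC"),
              outputs = outputs)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(man)
}
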