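#' Write and read session artefacts as delimited text
#'
#' Sessions and logs round-trip through plain CSV: a labels table
#' (`time_s,action_id`), an optional raw stream table
#' (`time_s,acc_ap,acc_ml,acc_dv,gyr_x,gyr_y,gyr_z`) and a trigger/event log
#' (`time_s,event`).
#'
#' @param session `labeled_session` from [simulate_session()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_session_csv <- function(session, dir, prefix = "session") {
  stopifnot(inherits(session, "labeled_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(labels = file.path(dir, paste0(prefix, "_labels.csv")))
  utils::write.csv(data.frame(time_s = session$times,
                              action_id = session$labels),
                   paths[["labels"]], row.names = FALSE)
  if (!is.null(session$stream)) {
    paths[["raw"]] <- file.path(dir, paste0(prefix, "_raw.csv"))
    s <- session$stream
    utils::write.csv(data.frame(time_s = s$time,
                                acc_ap = s$acc[, 1], acc_ml = s$acc[, 2],
                                acc_dv = s$acc[, 3], gyr_x = s$gyr[, 1],
                                gyr_y = s$gyr[, 2], gyr_z = s$gyr[, 3]),
                     paths[["raw"]], row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_session_csv
#' @param path labels CSV path.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "action_id") %in% names(df)))
  structure(list(labels = as.integer(df$action_id), times = df$time_s),
            class = "labeled_session")
}

#' @rdname write_session_csv
#' @export
read_raw_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "acc_ap", "acc_ml", "acc_dv", "gyr_x", "gyr_y", "gyr_z")
  stopifnot(all(need %in% names(df)))
  dt <- diff(df$time_s)
  raw_stream(as.matrix(df[, c("acc_ap", "acc_ml", "acc_dv")]),
             as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")]),
             sample_rate = 1 / stats::median(dt), t0 = df$time_s[1L])
}

#' Write a closed-loop session log as a tidy event table
#'
#' Events are `segment` (one row per classified segment, detail = action id)
#' and `trigger` (detail = train onset after latency).
#'
#' @param log `session_log` from [run_closed_loop()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_session_log_csv <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  ev <- rbind(
    data.frame(time_s = log$times, kind = "segment", detail = log$labels),
    if (nrow(log$triggers)) {
      data.frame(time_s = log$triggers$time, kind = "trigger",
                 detail = log$triggers$onset)
    })
  ev <- ev[order(ev$time_s), ]
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a repertoire's exemplars, labels and similarities to CSV
#'
#' Three tables: exemplar histogram bins (`action,feature,bin,mass`), segment
#' labels, and the exemplar similarity matrix. Bin masses round-trip at full
#' double precision so featurization stays bit-identical across platforms.
#'
#' @param rep `action_repertoire`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_repertoire_csv <- function(rep, dir) {
  stopifnot(inherits(rep, "action_repertoire"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- do.call(rbind, lapply(seq_along(rep$exemplars), function(i) {
    e <- rep$exemplars[[i]]
    do.call(rbind, lapply(names(e), function(f) {
      data.frame(action = i, feature = f, bin = seq_along(e[[f]]),
                 mass = e[[f]])
    }))
  }))
  paths <- c(exemplars = file.path(dir, "exemplars.csv"),
             labels = file.path(dir, "labels.csv"),
             similarity = file.path(dir, "similarity.csv"))
  write_full <- function(df, p) {
    con <- file(p, "w")
    on.exit(close(con))
    utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, quote = FALSE)
  }
  write_full(rows, paths[["exemplars"]])
  utils::write.csv(data.frame(segment = seq_along(rep$labels),
                              action_id = rep$labels),
                   paths[["labels"]], row.names = FALSE)
  write_full(as.data.frame(unclass(rep$S_ex)), paths[["similarity"]])
  invisible(paths)
}

#' @rdname write_repertoire_csv
#' @export
read_repertoire_csv <- function(dir) {
  ex <- utils::read.csv(file.path(dir, "exemplars.csv"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  exemplars <- lapply(split(ex, ex$action), function(d) {
    g <- function(f) d$mass[d$feature == f][order(d$bin[d$feature == f])]
    hist_set(g("gaap"), g("accdv"), g("gyrdv"), g("totba"))
  })
  as_action_repertoire(unname(exemplars), lab$action_id)
}
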