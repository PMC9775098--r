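#' Load a per-subject chest-device record
#'
#' Reads one subject's chest recording -- the eight chest channels
#' (3-axis accelerometer, ECG, EMG, EDA, temperature, respiration) plus an
#' integer label stream -- into a [channel_matrix()]. The expected file is
#' an RDS serialization of the per-subject record structure:
#' `list(chest = list(ACC = <n x 3 matrix>, ECG = <n>, EMG = <n>,
#' EDA = <n>, TEMP = <n>, RESP = <n>), label = <n>)`. The public
#' distribution ships the same structure as a Python pickle; convert once
#' with e.g.
#' `pandas.to_pickle`-loaded dicts written via `pyreadr`/`rpy2`, or:
#' \preformatted{
#' # python: d = pickle.load(open("S10.pkl","rb"), encoding="latin1")
#' #         then write d["signal"]["chest"] arrays + d["label"] to RDS
#' }
#' Channels recorded at different rates must be aligned to a common length
#' beforehand (decimate to the slowest rate; the loader refuses ragged
#' channels rather than fabricating samples).
#'
#' Labels are remapped through `label_map` (protocol code -> class code);
#' rows whose label has no mapping are dropped and the count reported. The
#' default map keeps codes 0-3 as
#' 0 = Meditation, 1 = Baseline, 2 = Stress, 3 = Amusement.
#'
#' @param path RDS file with the structure above.
#' @param label_map Named integer vector mapping raw label values
#'   (as names) to class codes.
#' @param subject_id Optional identifier stored as an attribute.
#' @return A [channel_matrix()] with 8 columns
#'   (ACC_x, ACC_y, ACC_z, ECG, EMG, EDA, TEMP, RESP).
#' @export
load_wesad_chest <- function(path,
                             label_map = c("0" = 0L, "1" = 1L,
                                           "2" = 2L, "3" = 3L),
                             subject_id = NULL) {
  rec <- readRDS(path)
  chest <- rec$chest
  need <- c("ACC", "ECG", "EMG", "EDA", "TEMP", "RESP")
  missing_keys <- setdiff(need, names(chest))
  if (length(missing_keys)) {
    stop("record is missing chest key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  acc <- as.matrix(chest$ACC)
  if (ncol(acc) != 3L) {
    stop("ACC must be a 3-column block (x, y, z)", call. = FALSE)
  }
  lens <- c(nrow(acc), vapply(chest[need[-1]], length, 0L),
            length(rec$label))
  if (length(unique(lens)) != 1L) {
    stop("chest channels and label stream are not aligned to a common ",
         "length (got ", paste(lens, collapse = "/"),
         "); decimate to the slowest rate first", call. = FALSE)
  }
  cols <- cbind(acc,
                as.numeric(chest$ECG), as.numeric(chest$EMG),
                as.numeric(chest$EDA), as.numeric(chest$TEMP),
                as.numeric(chest$RESP))
  colnames(cols) <- c("ACC_x", "ACC_y", "ACC_z", "ECG", "EMG", "EDA",
                      "TEMP", "RESP")
  raw_lab <- as.integer(rec$label)
  mapped <- label_map[as.character(raw_lab)]
  keep <- !is.na(mapped)
  if (any(!keep)) {
    message(sum(!keep), " rows with unmapped labels dropped")
  }
  if (!any(keep)) {
    stop("no rows remain after label mapping", call. = FALSE)
  }
  complete <- stats::complete.cases(cols)
  keep <- keep & complete
  cm <- channel_matrix(cols[keep, , drop = FALSE],
                       as.integer(mapped[keep]))
  attr(cm, "subject_id") <- subject_id
  cm
}

#' Load a delimited feature table with a label column
#'
#' Reads tabular stress-study features (rows = time points, columns =
#' features, one integer `label` column) into a [channel_matrix()],
#' selecting a feature subset of size `side` for the square image
#' encoding. The default takes the first `side` numeric columns; pass
#' `feature_cols` to choose explicitly. Rows with missing values in the
#' selected columns are dropped.
#'
#' @param path CSV file with a header.
#' @param side Number of feature columns to keep (the image side).
#' @param feature_cols Optional character vector of column names to use
#'   (length must equal `side`).
#' @param label_col Name of the label column.
#' @return A [channel_matrix()].
#' @export
load_swell <- function(path, side = 8L, feature_cols = NULL,
                       label_col = "label") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_col %in% names(df)) {
    stop("no `", label_col, "` column in ", path, call. = FALSE)
  }
  labels <- df[[label_col]]
  feats <- df[names(df) != label_col]
  numeric_cols <- names(feats)[vapply(feats, is.numeric, TRUE)]
  if (is.null(feature_cols)) {
    if (length(numeric_cols) < side) {
      stop("table has only ", length(numeric_cols), " numeric feature ",
           "columns but the image side is ", side, call. = FALSE)
    }
    feature_cols <- numeric_cols[seq_len(side)]
    if (length(numeric_cols) > side) {
      message("selected first ", side, " of ", length(numeric_cols),
              " numeric columns: ", paste(feature_cols, collapse = ", "))
    }
  } else {
    if (length(feature_cols) != side) {
      stop("`feature_cols` must have length ", side, call. = FALSE)
    }
    bad <- setdiff(feature_cols, numeric_cols)
    if (length(bad)) {
      stop("column(s) not present or not numeric: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  vals <- as.matrix(feats[feature_cols])
  keep <- stats::complete.cases(vals) & !is.na(labels)
  if (any(!keep)) message(sum(!keep), " incomplete rows dropped")
  channel_matrix(vals[keep, , drop = FALSE], as.integer(labels[keep]))
}
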