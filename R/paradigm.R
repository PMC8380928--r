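#' Roving-standard presentation plan
#'
#' Parameters of one roving-oddball block: a lead-in of repeated tokens of
#' stimulus A, followed by strictly alternating trains of stimulus B and
#' stimulus A. Train lengths are drawn pseudorandomly from
#' \code{train_lengths} under the constraint that, per stimulus, each length
#' occurs exactly \code{reps_per_length} times. The defaults reproduce the
#' standard block: 8-token lead-in, 100 trains per stimulus with lengths
#' 4-8 each 20 times, SOA 1.09 s (608 + 600 = 1208 tokens, 22 min).
#'
#' @param stim_a,stim_b stimulus labels; the lead-in uses \code{stim_a}.
#' @param lead_in number of lead-in tokens of \code{stim_a}.
#' @param train_lengths admissible train lengths.
#' @param reps_per_length occurrences of each length per stimulus.
#' @param soa stimulus onset asynchrony in seconds.
#' @param seed integer seed for the length pseudorandomization.
#' @return an object of class \code{roving_plan}.
#' @export
roving_plan <- function(stim_a = "fe220", stim_b = "fa220", lead_in = 8,
                        train_lengths = 4:8, reps_per_length = 20,
                        soa = 1.09, seed = 1L) {
  if (lead_in < 0) stop("lead_in must be non-negative")
  if (reps_per_length < 1) stop("reps_per_length must be at least 1")
  structure(list(stim_a = stim_a, stim_b = stim_b, lead_in = lead_in,
                 train_lengths = sort(unique(train_lengths)),
                 reps_per_length = reps_per_length,
                 trains_per_stim = length(unique(train_lengths)) * reps_per_length,
                 soa = soa, seed = as.integer(seed)),
            class = "roving_plan")
}

#' Generate a roving-standard event sequence
#'
#' Produces the full ordered event list for one block: \code{lead_in} tokens
#' of stimulus A (train id -1), then alternating trains starting with
#' stimulus B (a first A-train would be indistinguishable from the lead-in).
#' Per stimulus, the multiset of train lengths is exactly
#' \code{train_lengths} repeated \code{reps_per_length} times, in seeded
#' random order. Onsets are \code{(index - 1) * soa} seconds.
#'
#' @param plan a [roving_plan()].
#' @return an \code{event_list}: data frame with columns \code{index},
#'   \code{onset} (s), \code{stimulus}, \code{train_id},
#'   \code{position_in_train}, \code{role}; roles are assigned by
#'   [assign_roles()].
#' @export
generate_sequence <- function(plan) {
  stopifnot(inherits(plan, "roving_plan"))
  if (plan$trains_per_stim !=
      length(plan$train_lengths) * plan$reps_per_length)
    stop("inconsistent plan: trains_per_stim must equal lengths x reps")
  set.seed(plan$seed)
  shuffle <- function(x) x[sample.int(length(x))]   # safe for length-1 pools
  lengths_a <- shuffle(rep(plan$train_lengths, plan$reps_per_length))
  lengths_b <- shuffle(rep(plan$train_lengths, plan$reps_per_length))
  n_trains <- 2 * plan$trains_per_stim
  # trains alternate starting with stim_b
  train_stim <- rep(c(plan$stim_b, plan$stim_a), plan$trains_per_stim)
  train_len <- integer(n_trains)
  train_len[train_stim == plan$stim_a] <- lengths_a
  train_len[train_stim == plan$stim_b] <- lengths_b
  stimulus <- c(rep(plan$stim_a, plan$lead_in), rep(train_stim, train_len))
  train_id <- c(rep(-1L, plan$lead_in), rep(seq_len(n_trains), train_len))
  position <- c(seq_len(plan$lead_in), unlist(lapply(train_len, seq_len)))
  n <- length(stimulus)
  ev <- data.frame(index = seq_len(n), onset = (seq_len(n) - 1) * plan$soa,
                   stimulus = stimulus, train_id = train_id,
                   position_in_train = position, role = "filler",
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_list", "data.frame")
  assign_roles(ev)
}

#' Assign deviant/standard/filler roles within trains
#'
#' In a roving design roles follow within-train position: the first token of
#' each train is the deviant (it breaks the preceding regularity), the last
#' two tokens are the standards (the regularity is fully established by
#' then), intermediate tokens are fillers, and lead-in tokens get the
#' \code{lead_in} role and never enter averaging.
#'
#' @param events an \code{event_list} carrying \code{train_id} and
#'   \code{position_in_train}.
#' @return the event list with the \code{role} column filled in.
#' @export
assign_roles <- function(events) {
  stopifnot(all(c("train_id", "position_in_train") %in% names(events)))
  role <- rep("filler", nrow(events))
  role[events$train_id < 0] <- "lead_in"
  for (tid in unique(events$train_id[events$train_id > 0])) {
    idx <- which(events$train_id == tid)
    len <- length(idx)
    if (len < 3)
      stop("train ", tid, " has length ", len,
           ": deviant and standard roles would overlap (need >= 3)")
    role[idx[1]] <- "deviant"
    role[idx[c(len - 1, len)]] <- "standard"
  }
  events$role <- role
  class(events) <- c("event_list", "data.frame")
  events
}

#' Total block duration
#'
#' @param events an \code{event_list}.
#' @param plan the [roving_plan()] that generated it (for the SOA).
#' @return list with \code{seconds} (exact, events x SOA), \code{minutes}
#'   (exact) and \code{minutes_rounded}.
#' @export
total_duration <- function(events, plan) {
  if (nrow(events) == 0) stop("empty event list")
  secs <- nrow(events) * plan$soa
  list(seconds = secs, minutes = secs / 60, minutes_rounded = round(secs / 60))
}

#' Read and write event lists as tab-separated tables
#'
#' BIDS-events-like TSV with columns onset, duration, stimulus, train_id,
#' position_in_train, role. Reading validates the column set, row-wise
#' parseability, and that onsets are non-decreasing.
#'
#' @param events an \code{event_list}.
#' @param path TSV file path.
#' @param duration per-event duration column value in seconds (stimulus
#'   duration is not tracked per event; 0 by convention).
#' @return \code{path} invisibly (write); an \code{event_list} (read).
#' @export
write_events <- function(events, path, duration = 0) {
  out <- data.frame(onset = events$onset, duration = duration,
                    stimulus = events$stimulus, train_id = events$train_id,
                    position_in_train = events$position_in_train,
                    role = events$role)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  need <- c("onset", "duration", "stimulus", "train_id",
            "position_in_train", "role")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("events file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(tab$onset) | !is.finite(tab$train_id))
  if (length(bad))
    stop("malformed events rows (1-based, excluding header): ",
         paste(bad, collapse = ", "))
  if (any(diff(tab$onset) < 0))
    stop("onset column must be non-decreasing in ", path)
  ev <- data.frame(index = seq_len(nrow(tab)), onset = tab$onset,
                   stimulus = tab$stimulus, train_id = as.integer(tab$train_id),
                   position_in_train = as.integer(tab$position_in_train),
                   role = tab$role, stringsAsFactors = FALSE)
  class(ev) <- c("event_list", "data.frame")
  ev
}
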