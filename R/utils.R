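# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with call. = FALSE and sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# The ten shopping-list categories shown to every participant.
SHOPPING_LIST <- c(
  "savoury_pies", "cheese", "frozen_pizza", "sandwiches", "yogurt",
  "ready_meals", "meat_and_alternatives", "soup", "desserts", "crackers"
)

ARMS <- c("control", "health_position", "health_position_labels",
          "eco_position", "eco_position_labels")

LETTERS5 <- c("A", "B", "C", "D", "E")
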