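# Shared fixtures, built in code at test time.

fixture_dict <- function(seed = 7) build_fixture("liga6x5", seed = seed)

glycan_ids <- function(dict)
  dict$entries$entry_id[dict$entries$modification_class == "glycan"]

invariant_ids <- function(dict)
  dict$entries$entry_id[dict$entries$modification_class != "glycan"]

# a minimal 3-entry dictionary with hand-chosen silent barcodes
tiny_dict <- function() {
  entries <- data.frame(
    entry_id = c("e1", "e2", "e3"),
    library_id = "TD",
    sdb1 = c("AGTGTAGAA", "TCCGTTGAG", "AGCGTTGAA"),
    sdb2 = c("AAGTAT", "AAATAC", "AAGTAC"),
    modification_class = c("glycan", "glycan", "azidoethanol"),
    structure_id = c("Man3", "A2G2", ""),
    cfg_name = c("Man3", "A2G2", ""),
    composition = c("Hex:3;HexNAc:2", "Hex:5;HexNAc:4", ""),
    mean_density = c(500, 150, 0),
    stringsAsFactors = FALSE)
  liga_dictionary(entries, library_id = "TD")
}
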