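# Item metadata and binarization rules for the four self-report instruments.
#
# For an ordinary item, score >= binarize_cut codes 1 ("presence" /
# "empathic" / "emotionally expressive"); for a reverse-keyed item the
# complementary rule applies (score < binarize_cut codes 1).
DASS21:
  label: "DASS-21"
  n_items: 21
  scale_min: 0
  scale_max: 3
  binarize_cut: 1
  reversed_items: []
  subscales:
    depression: [3, 5, 10, 13, 16, 17, 21]
    anxiety: [2, 4, 7, 9, 15, 19, 20]
    stress: [1, 6, 8, 11, 12, 14, 18]
EQ_SHORT:
  label: "EQ-short"
  n_items: 11
  scale_min: 0
  scale_max: 3
  binarize_cut: 2
  reversed_items: []
  # 11-item Korean short form; positions 1..11 map to these items of the
  # 22-item EQ short form they were selected from.
  source_items: [1, 6, 9, 10, 13, 14, 16, 18, 19, 20, 21]
JSE_S:
  label: "JSE-S"
  n_items: 20
  scale_min: 1
  scale_max: 7
  binarize_cut: 4
  reversed_items: [1, 3, 6, 7, 8, 11, 12, 14]
EES:
  label: "EES"
  n_items: 17
  scale_min: 1
  scale_max: 5
  binarize_cut: 3
  reversed_items: [2, 3, 4, 7, 9, 10, 11, 12, 15, 16, 17]
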