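# Fixture transcription notes

The packaged peak tables (`diaporthe_peaks.csv`), MS/MS spectra
(`diaporthe_msms.json`) and reference common-ion table
(`reference_common_ions.csv`) are transcriptions of printed unit-resolution
peak lists for the two *Diaporthe melongenae* strains F0728 and F0891. Every
deviation from the printed source is recorded here.

## Peak tables

- F0891 / SDA / 15 d / positive: printed `180 (50.0;` — unbalanced
  parenthesis; transcribed as m/z 180 at 50.0%.
- F0891 / PDA / 7 d / positive: printed `351 (18.0;` — same defect;
  transcribed as m/z 351 at 18.0%.
- Several printed cells separate adjacent peaks with a space instead of a
  semicolon (e.g. `251 (14.8) 268 (14.8)`, `394 (38.0) 396 (50.1)`,
  `235 (20.0) 249 (32.3)`); treated as separators, peaks kept.
- Peaks are stored in ascending m/z per extract; the printed lists are
  already ascending, so no reordering was applied.

## MS/MS spectra

- Compound 6 (precursor 249, negative): `189 (12) [-CO2/H2O]` is printed
  twice; transcribed once. The printed losses of products 189 and 187 sum to
  62/64 Da although the observed differences are 60/62 Da; kept verbatim and
  flagged in the `note` field.
- Compound 5 (precursor 235, negative): printed losses `C3H9` and `C4H12`
  are chemically implausible neutral species; kept verbatim and flagged.
  `CHO` is not part of the default loss vocabulary; flagged.
- Compound 9 (precursor 207, positive): product 174 is printed with loss
  `-CH3` (15 Da) although the observed difference is 33 Da; kept and
  flagged.
- Compound 10 (precursor 217, negative): losses printed as `-C2H4O/H+` and
  `-C2H3O2/H+`; the `H+` token denotes the already-departed adduct proton of
  the [M-H]- precursor (the printed fragment masses only balance without
  it) and was dropped from the transcription, with a note.
- Compound 11 (precursor 245, positive): printed loss `C2H4` is not part of
  the default vocabulary; flagged.
- Compound 12 (precursor 343, positive): product 119 carries a
  five-component printed loss (`C9H18O/3H2O/CO`); noted because it exceeds
  the default combination-depth of 4.
- Multiplied losses (`2H2O`, `3H2O`) are expanded into repeated labels.
- `OHCH3`/`HOCH3` are normalised to `CH3OH`, `CH3O` to `OCH3`.
- Unbolded (lower-emphasis) product ions in the printed table carry
  `"unbold": true`; products printed without any loss annotation have no
  `losses` field.

## Compound library

- Nominal masses are derived from the printed adduct m/z values under the
  [M+H]+ / [M-H]- rules.
- Molecular formulas are included only where they could be reconstructed
  with confidence from the compound identity and nominal mass (compounds
  1-10); phomolide G, phomolide C and volemolide carry no formula and a
  note. Formulas are advisory annotations, not trusted fields.
- 22 synthetic decoy records (`decoy-400` ... `decoy-660`) sit at nominal
  masses whose adduct ions (mass ± 1) do not occur anywhere in the packaged
  peak tables; they keep identification tests non-circular.

## Reference common-ion table

- Transcribed as printed. Note that three ions satisfying the stated
  common-ion rule on the peak tables are absent from the printed reference:
  m/z 207 (MEA/22 d/positive), m/z 164 (SDA/15 d/positive) and m/z 165
  (SDA/7 d/negative). The pipeline reports them and warns; see
  `compare_common_ions()`.
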