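I:
  donor_id: I
  fractions:
    enucleated: 0.3
    nucleated: 0.45
    nucleus: 0.25
  dna_background:
    meanlog: 3.0
    sdlog: 0.4
  debris_fraction: 0.05
  classes:
    enucleated:
      area:
        mean: 48.0
        sd: 14.0
      deformability:
        mean: 0.045
        sd: 0.01
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 6.0
        sdlog: 0.4
    nucleated:
      area:
        mean: 80.0
        sd: 15.0
      deformability:
        mean: 0.02
        sd: 0.006
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 6.2
        sdlog: 0.4
    nucleus:
      area:
        mean: 40.0
        sd: 10.0
      deformability:
        mean: 0.012
        sd: 0.004
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 4.8
        sdlog: 0.5
II:
  donor_id: II
  fractions:
    enucleated: 0.12
    nucleated: 0.55
    nucleus: 0.33
  dna_background:
    meanlog: 3.0
    sdlog: 0.4
  debris_fraction: 0.05
  classes:
    enucleated:
      area:
        mean: 36.0
        sd: 9.0
      deformability:
        mean: 0.03
        sd: 0.008
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 6.0
        sdlog: 0.4
    nucleated:
      area:
        mean: 80.0
        sd: 15.0
      deformability:
        mean: 0.02
        sd: 0.006
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 6.2
        sdlog: 0.4
    nucleus:
      area:
        mean: 38.0
        sd: 9.0
      deformability:
        mean: 0.012
        sd: 0.004
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 4.8
        sdlog: 0.5
III:
  donor_id: III
  fractions:
    enucleated: 0.35
    nucleated: 0.45
    nucleus: 0.2
  dna_background:
    meanlog: 3.0
    sdlog: 0.4
  debris_fraction: 0.05
  classes:
    enucleated:
      area:
        mean: 71.0
        sd: 16.0
      deformability:
        mean: 0.045
        sd: 0.01
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 6.0
        sdlog: 0.4
    nucleated:
      area:
        mean: 74.3
        sd: 15.0
      deformability:
        mean: 0.02
        sd: 0.006
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 6.2
        sdlog: 0.4
    nucleus:
      area:
        mean: 40.0
        sd: 10.0
      deformability:
        mean: 0.012
        sd: 0.004
      dna:
        meanlog: 7.0
        sdlog: 0.5
      cd235a:
        meanlog: 4.8
        sdlog: 0.5
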