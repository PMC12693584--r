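# Human-like four-deme out-of-Africa history (approximate).
# Structure follows the classic three-population OOA model plus the
# ancestral deme; sizes/times are rounded literature-style values, with
# exponential growth discretized into stepwise epochs. Values are
# approximate stand-ins, not a published supplementary table.
"N": 7300
mu: 1.44e-8
r: 1.0e-8
burn_in: 112930
extra_generations: 12312
sample_n: 100
mean_exon_len: 300
mean_intron_len: 4200
target_exonic: 270000
ns_model:
  kind: gamma
  shape: 0.186
  scale_2Ns: 706.899
syn_model:
  kind: gamma
  shape: 0.14
  scale_2Ns: 55.0
demography:
  total_generations: 125242
  demes:
    - name: ancestral
      epochs:
        - {duration: 117322, size: 7300}
        - {duration: 7920, size: 12300}   # African expansion
    - name: AFR
      epochs:
        - {duration: 4280, size: 12300}
    - name: EUR
      epochs:
        - {duration: 570, size: 1000}
        - {duration: 570, size: 3300}
        - {duration: 570, size: 10800}
        - {duration: 570, size: 29700}
    - name: EAS
      epochs:
        - {duration: 570, size: 510}
        - {duration: 570, size: 2200}
        - {duration: 570, size: 9800}
        - {duration: 570, size: 45900}
  splits:
    - {time: 120962, parent: ancestral, child: AFR}   # OOA bottleneck split
    - {time: 122962, parent: AFR, child: EUR}
    - {time: 122962, parent: AFR, child: EAS}
  migration:
    - from_time: 120962
      rates:
        - {dest: AFR, src: ancestral, rate: 0.0}
    - from_time: 122962
      rates:
        - {dest: AFR, src: EUR, rate: 3.0e-5}
        - {dest: EUR, src: AFR, rate: 3.0e-5}
        - {dest: EUR, src: EAS, rate: 9.6e-5}
        - {dest: EAS, src: EUR, rate: 9.6e-5}
        - {dest: AFR, src: EAS, rate: 1.9e-5}
        - {dest: EAS, src: AFR, rate: 1.9e-5}
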