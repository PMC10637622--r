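# Example site configuration for `qvbridge run --config <this file>`.
# Directory transport: the inbox stands in for the inbound store service,
# the archive for the query/retrieve archive.
inbox_dir: inbox
archive_dir: archive
work_dir: work
series_filters:
  - portal venous
timeout_s: 30          # series-completion timeout, seconds
segmenter:
  name: reference_threshold
  params:
    hu_low: 40
    hu_high: 80
    keep_largest_component: false
    min_component_voxels: 0
# segment_metadata: segment_metadata_example.json
uid_root: "2.25.847190."
retries: 2
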