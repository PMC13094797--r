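# Demo study: a two-organization blood-donor cohort with donor, donation and
# testing tables. Everything study-specific -- dictionaries, QC policy,
# lookups, buckets, reports -- lives here; the code is study-agnostic.
study_id: demo_donor_cohort

qc_policy:
  UNKNOWN_COLUMN: warn

dictionaries:
  donor:
    level: 1
    append_only: false          # quarterly donor refreshes upsert with audit
    fields:
      - name: donor_id
        type: text
        max_length: 12
        required: true
        key: primary
      - name: birth_date
        type: date
        required: true
        date_bounds: ["1920-01-01", "2010-12-31"]
        pii_class: indirect
        privacy: truncate_date_to_month
        privacy_applied_at: import
      - name: blood_group
        type: code
        max_length: 3
        required: true
        allowed_codes: [A+, A-, B+, B-, AB+, AB-, O+, O-]
  donation:
    level: 2
    fields:
      - name: donation_id
        type: text
        max_length: 12
        required: true
        key: primary
      - name: donor_id
        type: text
        max_length: 12
        required: true
        key: foreign
        references: {table: donor, field: donor_id}
      - name: visit_date
        type: date
        required: true
        date_bounds: ["2020-01-01", "2026-12-31"]
      - name: zip_code
        type: text
        max_length: 5
        pii_class: indirect
        privacy: truncate_zip_to_3
        privacy_applied_at: import
      - name: race
        type: code
        max_length: 1
        allowed_codes: ['W', 'B', 'A', 'N', 'P', 'M', 'U']
      - name: ethnicity
        type: code
        max_length: 1
        allowed_codes: ['H', 'N', 'U']
      - name: sex
        type: code
        max_length: 1
        required: true
        allowed_codes: ['M', 'F', 'O']
  testing:
    level: 3
    fields:
      - name: result_id
        type: text
        max_length: 12
        required: true
        key: primary
      - name: donation_id
        type: text
        max_length: 12
        required: true
        key: foreign
        references: {table: donation, field: donation_id}
      - name: assay
        type: code
        max_length: 10
        required: true
        allowed_codes: [IGG_S, IGG_N, TOTAL_IG]
      - name: result_value
        type: decimal
        max_length: 10
        required: true
      - name: result_interpretation
        type: code
        max_length: 13
        required: true
        allowed_codes: [positive, negative, indeterminate]
      - name: test_date
        type: date
        required: true
        date_bounds: ["2020-01-01", "2026-12-31"]

lookups:
  - name: race_group
    source: {table: donation, field: race}
    versions:
      - version: 1
        mapping:
          W: White
          B: Black
          A: Asian
          'N': American Indian or Alaska Native
          P: Native Hawaiian or Pacific Islander
          M: Multiracial
          U: Unknown
      - version: 2
        mapping:
          W: White
          B: Black
          A: Asian or Pacific Islander
          'N': American Indian or Alaska Native
          P: Asian or Pacific Islander
          M: Multiracial
          U: Unknown
  - name: rh_factor
    source: {table: donor, field: blood_group}
    versions:
      - version: 1
        mapping:
          A+: positive
          B+: positive
          AB+: positive
          O+: positive
          A-: negative
          B-: negative
          AB-: negative
          O-: negative

buckets:
  - org_id: org1
    expected_tables: [donor, donation, testing]
    schedule: monthly
  - org_id: org2
    expected_tables: [donor, donation, testing]
    schedule: monthly

reports:
  - name: testing_report
    source:
      - table: testing
        fields: [result_id, donation_id, assay, result_value, result_interpretation, test_date]
    transforms:
      - kind: rename
        field: result_id
        to: specimen_result_id
    qc_hooks:
      - kind: required_when
        field: result_value
        when_field: result_interpretation
        equals: positive
    target_schema:
      level: 1
      fields:
        - name: specimen_result_id
          type: text
          max_length: 12
          required: true
          key: primary
        - name: donation_id
          type: text
          max_length: 12
          required: true
        - name: assay
          type: code
          max_length: 10
          required: true
          allowed_codes: [IGG_S, IGG_N, TOTAL_IG]
        - name: result_value
          type: decimal
          max_length: 10
        - name: result_interpretation
          type: code
          max_length: 13
          required: true
          allowed_codes: [positive, negative, indeterminate]
        - name: test_date
          type: date
          required: true
  - name: donation_report
    source:
      - table: donation
        fields: [donation_id, donor_id, visit_date, zip_code, race]
      - table: donor
        fields: [blood_group]
    transforms:
      - kind: lookup_recode
        field: race
        lookup: race_group
        to: race_group
      - kind: privacy
        field: zip_code
        transform: truncate_zip_to_3
    target_schema:
      level: 1
      fields:
        - name: donation_id
          type: text
          max_length: 12
          required: true
          key: primary
        - name: donor_id
          type: text
          max_length: 12
          required: true
        - name: visit_date
          type: date
          required: true
        - name: zip_code
          type: text
          max_length: 3
        - name: race_group
          type: text
          max_length: 40
        - name: blood_group
          type: code
          max_length: 3
          required: true
          allowed_codes: [A+, A-, B+, B-, AB+, AB-, O+, O-]

paths:
  bucket_root: buckets
  db_dir: study_db
credentials:
  transport: local-filesystem
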