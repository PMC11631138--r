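# Registry JSONL schema

One JSON object per line, one study record per object. Field names mirror
the public ClinicalTrials.gov API (v1 study-fields) vocabulary.

| Key              | Type             | Notes                                             |
|------------------|------------------|---------------------------------------------------|
| `NCTId`          | string, required | unique within a file                              |
| `OverallStatus`  | string, required | e.g. `Recruiting`, `Completed`; unknown values are preserved and treated as non-matching by filters |
| `StudyType`      | string, required | `Interventional`, `Observational`, `Expanded Access` |
| `MinimumAge`     | string           | `"18 Years"`, `"6 Months"`, `"N/A"`, or absent    |
| `MaximumAge`     | string           | same grammar as `MinimumAge`                      |
| `Gender`         | string, required | `All`, `Male`, `Female`                           |
| `Condition`      | array of strings, required | free-text condition terms               |
| `Locations`      | array of objects | each `{ "Zip": str, "Country": str, "Status": str? }`; `Zip` is truncated to its first 3 characters for US sites |
| `LeadSponsorClass` | string, required | raw class, e.g. `NIH`, `INDUSTRY`, `OTHER`, `FED`; mapped to analysis classes via the sponsor-class mapping (default `NIH -> NIH`, `INDUSTRY -> Industry`, `OTHER -> Academic/Other`, `FED`/other federal -> `OtherFederal`, anything else -> `Unknown`) |

Example line:

```json
{"NCTId":"NCT00000001","OverallStatus":"Recruiting","StudyType":"Interventional","MinimumAge":"18 Years","MaximumAge":"N/A","Gender":"All","Condition":["type 2 diabetes"],"Locations":[{"Zip":"372","Country":"United States","Status":"Recruiting"}],"LeadSponsorClass":"NIH"}
```

Age strings are parsed case-insensitively: `N Years` -> N, `N Months` ->
N/12, `N Weeks` -> N/52, `N Days` -> N/365.25, `N/A` or empty -> absent.
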