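{
  "note": "Canonical 24-entry alcohol hashtag list with beverage categories (14 beer, 5 wine, 3 liquor, 2 ambiguous). Some upstream summaries of this list cite 19 beer hashtags; the itemized list below is authoritative here.",
  "hashtags": [
    {"hashtag": "craftbeer", "category": "beer"},
    {"hashtag": "beer", "category": "beer"},
    {"hashtag": "ncbeer", "category": "beer"},
    {"hashtag": "brewery", "category": "beer"},
    {"hashtag": "stout", "category": "beer"},
    {"hashtag": "beeroclock", "category": "beer"},
    {"hashtag": "beergeek", "category": "beer"},
    {"hashtag": "beerporn", "category": "beer"},
    {"hashtag": "beers", "category": "beer"},
    {"hashtag": "instabeer", "category": "beer"},
    {"hashtag": "beertime", "category": "beer"},
    {"hashtag": "beerstagram", "category": "beer"},
    {"hashtag": "beerlover", "category": "beer"},
    {"hashtag": "beersnob", "category": "beer"},
    {"hashtag": "winetasting", "category": "wine"},
    {"hashtag": "wine", "category": "wine"},
    {"hashtag": "winelover", "category": "wine"},
    {"hashtag": "wines", "category": "wine"},
    {"hashtag": "redwine", "category": "wine"},
    {"hashtag": "bourbon", "category": "liquor"},
    {"hashtag": "whiskey", "category": "liquor"},
    {"hashtag": "whisky", "category": "liquor"},
    {"hashtag": "drinklocal", "category": "ambiguous"},
    {"hashtag": "drunktwitter", "category": "ambiguous"}
  ]
}
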