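date,type,name
2020-04-29,national,Showa Day
2020-05-03,national,Constitution Memorial Day
2020-05-04,national,Greenery Day
2020-05-05,national,Children's Day
2020-05-06,national,Substitute holiday (Constitution Memorial Day)
2020-07-23,national,Marine Day (moved for Olympic schedule)
2020-07-24,national,Sports Day (moved for Olympic schedule)
2020-08-10,national,Mountain Day (moved for Olympic schedule)
2020-09-21,national,Respect for the Aged Day
2020-09-22,national,Autumnal Equinox Day
2020-11-03,national,Culture Day
2020-11-23,national,Labor Thanksgiving Day
2021-01-01,national,New Year's Day
2021-01-11,national,Coming of Age Day
2021-02-11,national,National Foundation Day
2021-02-23,national,Emperor's Birthday
2021-03-20,national,Vernal Equinox Day
2021-04-29,national,Showa Day
2021-05-03,national,Constitution Memorial Day
2021-05-04,national,Greenery Day
2021-05-05,national,Children's Day
2021-07-22,national,Marine Day (moved for Olympic schedule)
2021-07-23,national,Sports Day (moved for Olympic schedule)
2021-08-08,national,Mountain Day (moved for Olympic schedule)
2021-08-09,national,Substitute holiday (Mountain Day)
2020-08-13,unofficial,Obon
2020-08-14,unofficial,Obon
2020-08-15,unofficial,Obon
2020-08-16,unofficial,Obon
2020-12-29,unofficial,Year-end
2020-12-30,unofficial,Year-end
2020-12-31,unofficial,Year-end
2021-01-02,unofficial,New Year span
2021-01-03,unofficial,New Year span
2021-08-13,unofficial,Obon
2021-08-14,unofficial,Obon
2021-08-15,unofficial,Obon
2021-08-16,unofficial,Obon
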