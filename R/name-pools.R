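# Bundled name pools for the synthetic generator. Sizes are a compromise:
# large enough that most entities differ in several attributes, small enough
# that tautonyms (distinct persons with identical names) occasionally occur,
# as they do in real registries.

#' Bundled first-name pool
#' @return character vector of normalized first names.
#' @export
reclink_first_names <- function() c(
  "james", "john", "robert", "michael", "william", "david", "richard",
  "joseph", "thomas", "charles", "christopher", "daniel", "matthew",
  "anthony", "donald", "mark", "paul", "steven", "andrew", "kenneth",
  "george", "joshua", "kevin", "brian", "edward", "ronald", "timothy",
  "jason", "jeffrey", "ryan", "jacob", "gary", "nicholas", "eric",
  "stephen", "jonathan", "larry", "justin", "scott", "brandon", "frank",
  "benjamin", "gregory", "samuel", "raymond", "patrick", "alexander",
  "jack", "dennis", "jerry", "tyler", "aaron", "henry", "douglas",
  "peter", "zachary", "walter", "harold", "jeremy", "ethan", "carl",
  "keith", "roger", "gerald", "arthur", "lawrence", "albert", "joe",
  "mary", "patricia", "jennifer", "linda", "elizabeth", "barbara",
  "susan", "jessica", "sarah", "karen", "nancy", "lisa", "margaret",
  "betty", "sandra", "ashley", "dorothy", "kimberly", "emily", "donna",
  "michelle", "carol", "amanda", "melissa", "deborah", "stephanie",
  "rebecca", "laura", "sharon", "cynthia", "kathleen", "amy", "shirley",
  "angela", "helen", "anna", "brenda", "pamela", "nicole", "samantha",
  "katherine", "emma", "ruth", "christine", "catherine", "debra",
  "rachel", "carolyn", "janet", "virginia", "maria", "heather", "diane",
  "julie", "joyce", "victoria", "olivia", "kelly", "christina", "joan",
  "evelyn", "judith", "megan", "andrea", "cheryl", "hannah", "jacqueline",
  "martha", "gloria", "teresa", "ann", "frances", "abigail", "alice",
  "judy", "sophia", "grace", "denise", "theodore", "vincent", "philip",
  "louis", "russell", "bobby", "eugene", "randy", "howard", "craig",
  "alan", "juan", "carlos", "luis", "jose", "miguel", "antonio"
)

#' Bundled surname pool
#' @return character vector of normalized surnames.
#' @export
reclink_last_names <- function() c(
  "smith", "johnson", "williams", "brown", "jones", "garcia", "miller",
  "davis", "rodriguez", "martinez", "hernandez", "lopez", "gonzalez",
  "wilson", "anderson", "thomas", "taylor", "moore", "jackson", "martin",
  "lee", "perez", "thompson", "white", "harris", "sanchez", "clark",
  "ramirez", "lewis", "robinson", "walker", "young", "allen", "king",
  "wright", "scott", "torres", "nguyen", "hill", "flores", "green",
  "adams", "nelson", "baker", "hall", "rivera", "campbell", "mitchell",
  "carter", "roberts", "gomez", "phillips", "evans", "turner", "diaz",
  "parker", "cruz", "edwards", "collins", "reyes", "stewart", "morris",
  "morales", "murphy", "cook", "rogers", "gutierrez", "ortiz", "morgan",
  "cooper", "peterson", "bailey", "reed", "kelly", "howard", "ramos",
  "kim", "cox", "ward", "richardson", "watson", "brooks", "chavez",
  "wood", "james", "bennett", "gray", "mendoza", "ruiz", "hughes",
  "price", "alvarez", "castillo", "sanders", "patel", "myers", "long",
  "ross", "foster", "jimenez", "powell", "jenkins", "perry", "russell",
  "sullivan", "bell", "coleman", "butler", "henderson", "barnes",
  "fisher", "vasquez", "simmons", "romero", "jordan", "patterson",
  "alexander", "hamilton", "graham", "reynolds", "griffin", "wallace",
  "moreno", "west", "cole", "hayes", "bryant", "herrera", "gibson",
  "ellis", "tran", "medina", "aguilar", "stevens", "murray", "ford",
  "castro", "marshall", "owens", "harrison", "fernandez", "mcdonald",
  "woods", "washington", "kennedy", "wells", "vargas", "henry", "chen",
  "freeman", "webb", "tucker", "guzman", "burns", "crawford", "olson",
  "simpson", "porter", "hunter", "gordon", "mendez", "silva", "shaw",
  "snyder", "mason", "dixon", "munoz", "hunt", "hicks", "holmes",
  "palmer", "wagner", "black", "robertson", "boyd", "rose", "stone",
  "salazar", "fox", "warren", "mills", "meyer", "rice", "schmidt",
  "daniels", "ferguson", "nichols", "stephens", "soto", "weaver", "ryan",
  "gardner", "payne", "grant", "dunn", "kelley", "spencer", "hawkins",
  "arnold", "pierce", "vazquez", "hansen", "peters", "santos", "hart",
  "bradley", "knight", "elliott", "cunningham", "duncan", "armstrong",
  "hudson", "carroll", "lane", "riley", "andrews", "alvarado", "ray",
  "delgado", "berry", "perkins", "hoffman", "johnston", "matthews",
  "pena", "richards", "contreras", "willis", "carpenter", "lawrence",
  "sandoval", "guerrero", "george", "chapman", "rios", "estrada",
  "ortega", "watkins", "greene", "nunez", "wheeler", "valdez", "harper",
  "burke", "larson", "santiago", "maldonado", "morrison", "franklin",
  "carlson", "austin", "dominguez", "carr", "lawson", "jacobs", "obrien",
  "lynch", "singh", "vega", "bishop", "montgomery", "oliver", "jensen",
  "harvey", "williamson", "gilbert", "dean", "sims", "espinoza", "howell",
  "li", "wong", "reid", "hanson", "le", "mccoy", "garrett", "burton",
  "fuller", "wang", "weber", "welch", "rojas", "lucas", "marquez",
  "fields", "park", "yang", "little", "banks", "padilla", "day", "walsh",
  "bowman", "schultz", "luna", "fowler", "mejia"
)

#' Bundled nickname pairs
#' @return two-column data.frame of (name, variant) pairs.
#' @export
reclink_nickname_pairs <- function() {
  p <- matrix(c(
    "james", "jim",       "james", "jimmy",
    "john", "jack",       "john", "johnny",
    "robert", "bob",      "robert", "rob",      "robert", "bobby",
    "michael", "mike",    "william", "bill",    "william", "will",
    "william", "billy",   "david", "dave",      "richard", "rick",
    "richard", "dick",    "joseph", "joe",      "joseph", "joey",
    "thomas", "tom",      "thomas", "tommy",    "charles", "charlie",
    "charles", "chuck",   "christopher", "chris", "daniel", "dan",
    "daniel", "danny",    "matthew", "matt",    "anthony", "tony",
    "donald", "don",      "steven", "steve",    "andrew", "andy",
    "andrew", "drew",     "kenneth", "ken",     "kenneth", "kenny",
    "joshua", "josh",     "edward", "ed",       "edward", "eddie",
    "edward", "ted",      "ronald", "ron",      "timothy", "tim",
    "jeffrey", "jeff",    "jacob", "jake",      "nicholas", "nick",
    "stephen", "steve",   "jonathan", "jon",    "lawrence", "larry",
    "justin", "jus",      "benjamin", "ben",    "gregory", "greg",
    "samuel", "sam",      "raymond", "ray",     "patrick", "pat",
    "alexander", "alex",  "dennis", "denny",    "gerald", "jerry",
    "tyler", "ty",        "zachary", "zach",    "walter", "walt",
    "jeremy", "jem",      "douglas", "doug",    "peter", "pete",
    "arthur", "art",      "albert", "al",       "theodore", "ted",
    "theodore", "theo",   "vincent", "vince",   "philip", "phil",
    "louis", "lou",       "russell", "russ",    "eugene", "gene",
    "randy", "randall",   "howard", "howie",    "frank", "frankie",
    "mary", "molly",      "patricia", "pat",    "patricia", "patty",
    "patricia", "trish",  "jennifer", "jen",    "jennifer", "jenny",
    "elizabeth", "liz",   "elizabeth", "beth",  "elizabeth", "betsy",
    "elizabeth", "eliza", "barbara", "barb",    "susan", "sue",
    "susan", "susie",     "jessica", "jess",    "sarah", "sally",
    "karen", "kaz",       "nancy", "nan",       "margaret", "maggie",
    "margaret", "peggy",  "margaret", "meg",    "sandra", "sandy",
    "dorothy", "dot",     "dorothy", "dottie",  "kimberly", "kim",
    "emily", "em",        "michelle", "shelly", "amanda", "mandy",
    "melissa", "mel",     "deborah", "deb",     "deborah", "debbie",
    "stephanie", "steph", "rebecca", "becky",   "kathleen", "kathy",
    "kathleen", "kate",   "angela", "angie",    "helen", "nell",
    "brenda", "bren",     "pamela", "pam",      "nicole", "nikki",
    "samantha", "sam",    "katherine", "kate",  "katherine", "katie",
    "katherine", "kathy", "christine", "chris", "christine", "chrissy",
    "catherine", "cathy", "catherine", "cat",   "debra", "deb",
    "rachel", "rae",      "virginia", "ginny",  "victoria", "vicky",
    "victoria", "tori",   "christina", "tina",  "judith", "judy",
    "megan", "meg",       "cheryl", "sherry",   "jacqueline", "jackie",
    "gloria", "glo",      "teresa", "terry",    "frances", "fran",
    "abigail", "abby",    "sophia", "sophie",   "denise", "dee",
    "joan", "joanie",     "evelyn", "evie",     "hannah", "annie",
    "martha", "marty",    "carolyn", "carrie",  "cynthia", "cindy"
  ), ncol = 2, byrow = TRUE)
  data.frame(name = p[, 1], variant = p[, 2], stringsAsFactors = FALSE)
}
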